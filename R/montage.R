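#' Channel montage with functional role subsets
#'
#' A montage names the recorded 10-20 electrode sites, in order, and assigns
#' the subsets used by the neurometrics: frontal and parietal pools for the
#' workload index, and right/left frontal pools for the approach-withdrawal
#' (frontal alpha asymmetry) index.
#'
#' The default is the 8-site prefrontal/parietal montage
#' AFz, AF3, AF4, AF7, AF8, Pz, P3, P4. Default roles: workload frontal =
#' all five AF sites, workload parietal = Pz, P3, P4; asymmetry right =
#' AF4, AF8, left = AF3, AF7 (the midline AFz belongs to neither hemisphere
#' and is excluded from the asymmetry pools).
#'
#' @param labels ordered channel labels (10-20 names).
#' @param frontal,parietal labels of the workload-index channel pools.
#' @param frontal_right,frontal_left labels of the asymmetry pools; must be
#'   disjoint.
#' @return an object of class `eeg_montage`.
#' @examples
#' m <- channel_montage()
#' m$frontal_right
#' @export
channel_montage <- function(labels = c("AFz", "AF3", "AF4", "AF7", "AF8",
                                       "Pz", "P3", "P4"),
                            frontal = c("AFz", "AF3", "AF4", "AF7", "AF8"),
                            parietal = c("Pz", "P3", "P4"),
                            frontal_right = c("AF4", "AF8"),
                            frontal_left = c("AF3", "AF7")) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate channel labels in montage")
  for (nm in c("frontal", "parietal", "frontal_right", "frontal_left")) {
    sub <- get(nm)
    missing <- setdiff(sub, labels)
    if (length(missing)) {
      stop(sprintf("montage role '%s' uses unknown label(s): %s",
                   nm, paste(missing, collapse = ", ")))
    }
  }
  if (length(intersect(frontal_right, frontal_left))) {
    stop("frontal_right and frontal_left must be disjoint")
  }
  structure(
    list(labels = labels, frontal = frontal, parietal = parietal,
         frontal_right = frontal_right, frontal_left = frontal_left),
    class = "eeg_montage"
  )
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("EEG montage (", length(x$labels), " channels): ",
      paste(x$labels, collapse = " "), "\n", sep = "")
  cat("  frontal:       ", paste(x$frontal, collapse = " "), "\n")
  cat("  parietal:      ", paste(x$parietal, collapse = " "), "\n")
  cat("  frontal right: ", paste(x$frontal_right, collapse = " "), "\n")
  cat("  frontal left:  ", paste(x$frontal_left, collapse = " "), "\n")
  invisible(x)
}

montage_idx <- function(montage, role) {
  match(montage[[role]], montage$labels)
}
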