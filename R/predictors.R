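#' Describe a variant-effect predictor
#'
#' A predictor configuration records the sign convention and observed score
#' range of one predictor so that thresholding, rescaling and tail
#' selection are orientation-aware.
#'
#' @param name predictor name.
#' @param orientation `+1` if a larger raw score means more deleterious
#'   (SNAP2-, PoPMuSiC-style), `-1` if a smaller raw score does
#'   (EVmutation-style).
#' @param observed_min,observed_max raw score range observed in the
#'   reference dataset; used by [rescale_to_weight()].
#' @param arbitrary_threshold the predictor's shipped ad hoc cutoff.
#' @return a list of class `predictor_config`.
#' @seealso [default_predictors()]
#' @export
predictor_config <- function(name, orientation, observed_min, observed_max,
                             arbitrary_threshold = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            orientation %in% c(-1, 1),
            is.numeric(observed_min), is.numeric(observed_max),
            observed_min < observed_max)
  structure(list(name = name, orientation = orientation,
                 observed_min = observed_min, observed_max = observed_max,
                 arbitrary_threshold = arbitrary_threshold),
            class = "predictor_config")
}

#' @export
print.predictor_config <- function(x, ...) {
  cat(sprintf(
    "predictor '%s': orientation %+d, observed range [%g, %g], arbitrary threshold %g\n",
    x$name, x$orientation, x$observed_min, x$observed_max,
    x$arbitrary_threshold))
  invisible(x)
}

#' Default predictor configurations
#'
#' Configurations for the three predictors the calibration approach was
#' developed on.  Observed ranges are those of the reference clinical
#' dataset: EVmutation from -12.933 to 3.8104 (smaller = more deleterious,
#' arbitrary threshold 0), SNAP2 from -98 to 99 and PoPMuSiC 2.1 from
#' -1.90 to 5.64 (both larger = more deleterious).
#'
#' @param names subset of `c("EVmutation", "SNAP2", "PoPMuSiC")` to return.
#' @return named list of [predictor_config()] objects.
#' @export
default_predictors <- function(names = c("EVmutation", "SNAP2")) {
  all <- list(
    EVmutation = predictor_config("EVmutation", orientation = -1,
                                  observed_min = -12.933,
                                  observed_max = 3.8104,
                                  arbitrary_threshold = 0),
    SNAP2 = predictor_config("SNAP2", orientation = +1,
                             observed_min = -98, observed_max = 99,
                             arbitrary_threshold = 0),
    PoPMuSiC = predictor_config("PoPMuSiC", orientation = +1,
                                observed_min = -1.90, observed_max = 5.64,
                                arbitrary_threshold = 0))
  bad <- setdiff(names, names(all))
  if (length(bad)) stop("unknown predictor(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  all[names]
}

as_predictor_list <- function(predictors) {
  if (inherits(predictors, "predictor_config")) {
    predictors <- list(predictors)
  }
  stopifnot(all(vapply(predictors, inherits, logical(1), "predictor_config")))
  names(predictors) <- vapply(predictors, `[[`, character(1), "name")
  predictors
}
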