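#' Clarke error grid zone of a predicted glucose value
#'
#' Assigns each (reference, predicted) pair to one of the five zones of the
#' Clarke error grid using the original piecewise-linear boundaries:
#' \itemize{
#'   \item A: prediction within 20\% of the reference, or both below 70 mg/dL
#'     (clinically accurate);
#'   \item E: reference >= 180 with prediction <= 70, or reference <= 70 with
#'     prediction >= 180 (erroneous, opposite treatment);
#'   \item C: overcorrection zones (reference in [70, 290] with prediction
#'     >= reference + 110, or reference in [130, 180] with prediction
#'     <= (7/5) reference - 182);
#'   \item D: dangerous failure to detect (reference >= 240 with prediction in
#'     [70, 180], reference <= 175/3 with prediction in [70, 180], or
#'     reference in [175/3, 70] with prediction >= (6/5) reference);
#'   \item B: everything else (benign deviation).
#' }
#' The if/else cascade makes zone assignment a total function on
#' (0, 600]^2: every pair receives exactly one zone.
#'
#' @param reference reference glucose, mg/dL, in (0, 600].
#' @param predicted predicted glucose, mg/dL, in (0, 600] (vectorised;
#'   recycled against \code{reference}).
#' @return factor with levels A--E.
#' @examples
#' clarkeZone(c(100, 65, 190), c(100, 65, 65))  # A A E
#' @export
clarkeZone <- function(reference, predicted) {
  n <- max(length(reference), length(predicted))
  r <- rep_len(as.numeric(reference), n)
  p <- rep_len(as.numeric(predicted), n)
  if (any(!is.finite(c(r, p))) || any(c(r, p) <= 0) || any(c(r, p) > 600))
    stop("reference and predicted glucose must lie in (0, 600] mg/dL")
  zone <- character(n)
  inA <- (r <= 70 & p <= 70) | (p <= 1.2 * r & p >= 0.8 * r)
  inE <- !inA & ((r >= 180 & p <= 70) | (r <= 70 & p >= 180))
  inC <- !inA & !inE &
    ((r >= 70 & r <= 290 & p >= r + 110) |
     (r >= 130 & r <= 180 & p <= (7 / 5) * r - 182))
  inD <- !inA & !inE & !inC &
    ((r >= 240 & p >= 70 & p <= 180) |
     (r <= 175 / 3 & p <= 180 & p >= 70) |
     (r >= 175 / 3 & r <= 70 & p >= (6 / 5) * r))
  zone[inA] <- "A"; zone[inE] <- "E"; zone[inC] <- "C"; zone[inD] <- "D"
  zone[zone == ""] <- "B"
  factor(zone, levels = c("A", "B", "C", "D", "E"))
}

#' Tabulate Clarke zones
#'
#' @param reference,predicted as in [clarkeZone()].
#' @return named integer vector of counts over zones A--E.
#' @export
clarkeZoneCounts <- function(reference, predicted) {
  table(clarkeZone(reference, predicted))
}
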