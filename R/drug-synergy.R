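## Bliss-independence scoring of checkerboard viability matrices.

#' Fractional inhibition from percent viability
#'
#' `max(0, 1 - viability / 100)`; viability above the control (over 100%)
#' clamps to zero inhibition.
#'
#' @param viability_percent Viability as % of the untreated control (>= 0).
#' @return Fractional inhibition in \[0, 1\].
#' @export
inhibition <- function(viability_percent) {
  if (any(viability_percent < 0)) stop("negative viability")
  out <- 1 - viability_percent / 100
  out[out < 0] <- 0   # viability above control clamps to no inhibition
  out
}

#' Bliss-expected combined inhibition
#'
#' The independence null `e_a + e_b - e_a * e_b` for two agents with
#' single-agent fractional inhibitions `e_a` and `e_b`.
#'
#' @param e_a,e_b Fractional inhibitions in \[0, 1\].
#' @return Expected combined fractional inhibition.
#' @export
bliss_expected <- function(e_a, e_b) {
  if (any(e_a < 0 | e_a > 1 | e_b < 0 | e_b > 1))
    stop("inhibitions must lie in [0, 1]")
  e_a + e_b - e_a * e_b
}

#' Bliss synergy score for a checkerboard matrix
#'
#' For every combination cell (both doses > 0) the excess is
#' `(observed inhibition - Bliss-expected inhibition) * 100` percentage
#' points, with the expectation computed from the single-agent row and
#' column. The average score is the mean excess over all combination
#' cells; an average in `(-10, 10]` is additive, above 10 synergistic,
#' at or below -10 antagonistic. Replicate matrices are averaged
#' cell-wise before scoring.
#'
#' @param dm A `"dose_matrix"`, or a list of replicate `"dose_matrix"`
#'   objects on identical dose grids.
#' @return Object of class `"synergy_result"`: `excess_matrix`
#'   (combination cells only, in percentage points), `average_score`,
#'   `classification`.
#' @export
#' @examples
#' v <- rbind(c(100, 75), c(60, 45))  # doses 0/1 x 0/1
#' bliss_score(dose_matrix(c(0, 1), c(0, 1), v))
bliss_score <- function(dm) {
  if (is.list(dm) && !inherits(dm, "dose_matrix")) {
    if (length(dm) == 0L) stop("empty replicate list")
    base <- dm[[1]]
    for (rep_dm in dm) {
      stopifnot(inherits(rep_dm, "dose_matrix"))
      if (!identical(rep_dm$drug_a_doses, base$drug_a_doses) ||
          !identical(rep_dm$drug_b_doses, base$drug_b_doses))
        stop("replicate dose grids differ")
    }
    v <- Reduce(`+`, lapply(dm, `[[`, "viability")) / length(dm)
    dm <- dose_matrix(base$drug_a_doses, base$drug_b_doses, v)
  }
  stopifnot(inherits(dm, "dose_matrix"))
  na <- length(dm$drug_a_doses); nb <- length(dm$drug_b_doses)
  if (na < 2L || nb < 2L)
    stop("dose matrix needs the single-agent row/column plus >= 1 dose")
  inh <- inhibition(dm$viability)
  e_a <- inh[, 1]   # drug A alone (column of dose-0 drug B)
  e_b <- inh[1, ]   # drug B alone
  expected <- outer(e_a[-1], e_b[-1], bliss_expected)
  excess <- (inh[-1, -1, drop = FALSE] - expected) * 100
  dimnames(excess) <- list(dm$drug_a_doses[-1], dm$drug_b_doses[-1])
  avg <- mean(excess)
  classification <- if (avg > 10) "synergistic"
                    else if (avg > -10) "additive"
                    else "antagonistic"
  structure(list(excess_matrix = excess, average_score = avg,
                 classification = classification),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("Bliss synergy: average score %.2f (%s) over %d combination cells\n",
              x$average_score, x$classification, length(x$excess_matrix)))
  invisible(x)
}

#' Export a synergy result
#'
#' @param result A `"synergy_result"`.
#' @param json_path JSON path for `average_score` / `classification`
#'   (NULL to skip).
#' @param csv_path CSV path for the excess matrix (NULL to skip).
#' @return `result`, invisibly.
#' @export
write_synergy_result <- function(result, json_path = NULL,
                                 csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(list(average_score = result$average_score,
                              classification = result$classification),
                         json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(result$excess_matrix, csv_path)
  invisible(result)
}
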