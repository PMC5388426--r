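#' Experimental error budget
#'
#' The three experimental error layers between a nascent RNA and a base call:
#' reverse transcription, PCR amplification and sequencing. Under the
#' small-rate additive model they compose to a single per-base experimental
#' error probability `p_exp = p_rt + n_cycles * p_pcr + p_seq` (cross terms
#' are below 1e-6 and are neglected). A genuine mismatch hit by a
#' superimposed experimental error has a two-in-three chance of remaining
#' mismatched (the new base is one of three alternatives, one of which is the
#' template), captured by `f_retain = 2/3`.
#'
#' @param p_rt reverse-transcription errors per base (default 1e-4, the upper
#'   end of the documented 1e-4 to 1e-5 range for non-proofreading RTs).
#' @param p_pcr PCR errors per base per cycle (default 4e-7, a declared
#'   default for a high-fidelity polymerase).
#' @param n_cycles PCR cycles (default 15, declared default).
#' @param p_seq sequencing miscalls per base surviving the Phred filter
#'   (default 1e-3, the miscall rate at a Phred-30 threshold).
#' @param f_retain probability a genuine mismatch remains mismatched after a
#'   superimposed error (default 2/3).
#' @return an `error_budget` list with the rates and the derived `p_exp`.
#' @export
error_budget <- function(p_rt = 1e-4, p_pcr = 4e-7, n_cycles = 15,
                         p_seq = 1e-3, f_retain = 2 / 3) {
  stopifnot_prob(c(p_rt, p_pcr, p_seq, f_retain), "error budget rates")
  if (n_cycles < 0) stop("n_cycles must be non-negative")
  p_exp <- p_rt + n_cycles * p_pcr + p_seq
  if (p_exp >= 1) stop("combined experimental error rate must be below 1")
  structure(list(p_rt = p_rt, p_pcr = p_pcr, n_cycles = n_cycles,
                 p_seq = p_seq, f_retain = f_retain, p_exp = p_exp),
            class = "error_budget")
}

#' @export
print.error_budget <- function(x, ...) {
  cat(sprintf(
    "Error budget: RT %.2g + PCR %d x %.2g + sequencing %.2g = %.4g per base (retain %.3f)\n",
    x$p_rt, x$n_cycles, x$p_pcr, x$p_seq, x$p_exp, x$f_retain))
  invisible(x)
}

#' Observed mismatch rate expected from a true misincorporation rate
#'
#' False positives: a correctly transcribed base read as a mismatch with
#' probability `p_exp`. False negatives: a genuine mismatch hit by an
#' experimental error reverts to the template with probability
#' `p_exp * (1 - f_retain)`. Hence
#' `r_obs = r_true * (1 - p_exp * (1 - f_retain)) + (1 - r_true) * p_exp`.
#'
#' @param r_true true misincorporation rate at an offset, in `[0, 1]`.
#' @param budget an [error_budget()].
#' @return expected observed mismatch rate.
#' @export
expected_observed_rate <- function(r_true, budget = error_budget()) {
  stopifnot_prob(r_true, "r_true")
  p <- budget$p_exp
  r_true * (1 - p * (1 - budget$f_retain)) + (1 - r_true) * p
}

#' True-positive fraction of observed mismatches
#'
#' Inverts [expected_observed_rate()] for the true rate and reports the
#' percentage of observed mismatches that are genuine misincorporations
#' (true positives) rather than experimental errors. Observed rates at or
#' below the pure-noise floor `p_exp` give a true rate of zero, with a
#' warning.
#'
#' @param r_obs observed mismatch rate(s) at an offset, in `[0, 1]`.
#' @param budget an [error_budget()].
#' @return tibble (`accuracy_estimate`): r_obs, r_true,
#'   tp_fraction_percent.
#' @export
true_positive_fraction <- function(r_obs, budget = error_budget()) {
  stopifnot_prob(r_obs, "r_obs")
  p <- budget$p_exp
  keep <- 1 - p * (1 - budget$f_retain)  # genuine mismatch survives
  r_true <- (r_obs - p) / (keep - p)
  if (any(r_true < 0)) {
    warning("observed rate below the experimental noise floor; true rate clipped at 0")
    r_true <- pmax(r_true, 0)
  }
  tp <- ifelse(r_obs > 0, 100 * r_true * keep / r_obs, 0)
  out <- tibble::tibble(r_obs = r_obs, r_true = r_true,
                        tp_fraction_percent = tp)
  class(out) <- c("accuracy_estimate", class(out))
  out
}

#' Accuracy estimates for a positional error table
#'
#' Applies the error-propagation model to the observed total rate at every
#' offset, estimating how much of each position's signal is genuine.
#'
#' @param table a [positional_error_table()].
#' @param budget an [error_budget()].
#' @return tibble: offset, r_obs, r_true, tp_fraction_percent.
#' @export
accuracy_by_offset <- function(table, budget = error_budget()) {
  tot <- table$total[!is.na(table$total$total_rate_percent), , drop = FALSE]
  est <- suppressWarnings(
    true_positive_fraction(tot$total_rate_percent / 100, budget))
  tibble::tibble(offset = tot$offset, r_obs = est$r_obs, r_true = est$r_true,
                 tp_fraction_percent = est$tp_fraction_percent)
}
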