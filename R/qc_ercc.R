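# ERCC spike-in quality control: per-sample linearity of measured FPKM
# against the assigned mix's theoretical concentration, spike-fraction
# anomaly flags with a fixed precedence.

# Closed-form simple least squares of y on x: slope and R^2.
ls_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  r2 <- if (syy == 0 && sxx > 0) 1 else (sxy^2) / (sxx * syy)
  list(slope = slope, r_squared = r2)
}

#' Per-sample ERCC spike-in quality control
#'
#' Spike rows are identified by the `ERCC-` id prefix. For each sample, the
#' measured spike FPKM (plus a small pseudocount) is regressed in log-log
#' space on the assigned mix's theoretical concentration, over spikes with
#' measured signal above zero; undetected spikes are excluded from the fit
#' but count toward the detection threshold. Flags, in precedence order:
#' `missing_spike_in` (fewer than `min_detected` detected spikes, or spike
#' fraction below `min_fraction`), `excess_spike_in` (fraction above
#' `max_fraction`, e.g. RNA degradation), `poor_linearity` (R^2 below
#' `min_r2`), otherwise `ok`. The fraction bounds are stated on the FPKM
#' scale (share of summed FPKM), an analogue of — not an equivalence to —
#' read-fraction bounds.
#'
#' @param matrix FPKM matrix containing `ERCC-*` rows.
#' @param ref Spike reference table (`spike_id`, `mix1_concentration`,
#'   `mix2_concentration`).
#' @param mix_assignment Named character vector `sample_id -> "Mix1"|"Mix2"`.
#' @param min_r2 Minimum acceptable R^2.
#' @param min_fraction,max_fraction Acceptable band for the spike share of
#'   the sample's summed FPKM.
#' @param min_detected Minimum number of detected spikes for a usable fit.
#' @param fc_pseudocount Pseudocount on the measured side of the regression.
#' @return data.frame of class `bm_ercc_report`: `sample_id`, `mix`,
#'   `n_detected`, `r_squared`, `slope`, `spike_fraction`, `flag`.
#' @export
ercc_qc <- function(matrix, ref, mix_assignment, min_r2 = 0.8,
                    min_fraction = 0.001, max_fraction = 0.03,
                    min_detected = 8L, fc_pseudocount = 0.01) {
  spike_rows <- grep("^ERCC-", rownames(matrix), value = TRUE)
  if (!length(spike_rows)) stopf("matrix contains no ERCC spike rows")
  missing_assign <- setdiff(colnames(matrix), names(mix_assignment))
  if (length(missing_assign)) {
    stopf("sample(s) without a mix assignment: %s", fmt_ids(missing_assign))
  }
  idx <- match(spike_rows, ref$spike_id)
  if (anyNA(idx)) {
    stopf("spike row(s) absent from the reference: %s",
          fmt_ids(spike_rows[is.na(idx)]))
  }
  ref <- ref[idx, , drop = FALSE]

  out <- lapply(colnames(matrix), function(s) {
    mix <- mix_assignment[[s]]
    conc <- if (mix == "Mix1") ref$mix1_concentration else ref$mix2_concentration
    measured <- matrix[spike_rows, s]
    detected <- measured > 0
    total <- sum(matrix[, s])
    frac <- if (total > 0) sum(measured) / total else 0
    r2 <- NA_real_; slope <- NA_real_
    if (sum(detected) >= 2L) {
      fit <- ls_fit(log2(conc[detected]),
                    log2(measured[detected] + fc_pseudocount))
      r2 <- fit$r_squared; slope <- fit$slope
    }
    flag <- if (sum(detected) < min_detected || frac < min_fraction) {
      "missing_spike_in"
    } else if (frac > max_fraction) {
      "excess_spike_in"
    } else if (is.na(r2) || r2 < min_r2) {
      "poor_linearity"
    } else {
      "ok"
    }
    data.frame(sample_id = s, mix = mix, n_detected = sum(detected),
               r_squared = r2, slope = slope, spike_fraction = frac,
               flag = flag, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("bm_ercc_report", "data.frame"))
}
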