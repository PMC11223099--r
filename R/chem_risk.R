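#' Physicochemical phospholipidosis (DIPL) risk score
#'
#' Cationic amphiphilic drugs induce phospholipidosis in proportion to
#' their basicity and lipophilicity; the screening score
#' \eqn{pK_a^2 + cLogP^2} captures this. Scores strictly between the band
#' endpoints (default 75-85) are inconclusive: DIPL activity is not
#' reliably predicted there. Scores at or below the lower endpoint fall
#' below the band (low predicted risk) and at or above the upper endpoint
#' above it (high predicted risk); the band is read with strict
#' inequalities, so exact endpoint scores are conclusive.
#'
#' @param pKa Most basic center pKa, in `[0, 14]`.
#' @param cLogP Calculated logP; finite.
#' @param band Length-2 numeric band `(lower, upper)`, default `c(75, 85)`.
#' @return A `dipl_risk`: list with `score`, `zone` (one of `below_band`,
#'   `inconclusive`, `above_band`), `band`.
#' @export
dipl_score <- function(pKa, cLogP, band = c(75, 85)) {
  if (!is.finite(pKa) || !is.finite(cLogP)) {
    srs_error("srsphasor_invalid_parameter", "pKa and cLogP must be finite")
  }
  if (pKa < 0 || pKa > 14) {
    srs_error("srsphasor_invalid_parameter", "pKa must be in [0, 14]")
  }
  if (length(band) != 2 || band[1] >= band[2]) {
    srs_error("srsphasor_invalid_parameter", "band must satisfy band[1] < band[2]")
  }
  score <- pKa^2 + cLogP^2
  zone <- if (score >= band[2]) "above_band"
          else if (score <= band[1]) "below_band"
          else "inconclusive"
  structure(list(score = score, zone = zone, band = band),
            class = "dipl_risk")
}

#' Annotate a compound table with DIPL risk scores
#'
#' Adds `score` and `zone` columns to a table of compounds with `pKa` and
#' `cLogP` columns. Row order and all other columns are preserved.
#'
#' @param compounds data.frame, or path to a CSV, with columns `name`,
#'   `pKa`, `cLogP` (further columns pass through).
#' @param band Score band passed to [dipl_score()].
#' @param out Optional CSV path to write the annotated table to.
#' @return The annotated data.frame.
#' @export
score_table <- function(compounds, band = c(75, 85), out = NULL) {
  if (is.character(compounds)) {
    compounds <- utils::read.csv(compounds, stringsAsFactors = FALSE)
  }
  for (col in c("pKa", "cLogP")) {
    if (!col %in% names(compounds)) {
      srs_error("srsphasor_schema",
                sprintf("required column '%s' is missing", col))
    }
  }
  if (nrow(compounds)) {
    scored <- lapply(seq_len(nrow(compounds)), function(i) {
      dipl_score(compounds$pKa[i], compounds$cLogP[i], band)
    })
    compounds$score <- vapply(scored, `[[`, numeric(1), "score")
    compounds$zone <- vapply(scored, `[[`, character(1), "zone")
  } else {
    compounds$score <- numeric(0)
    compounds$zone <- character(0)
  }
  if (!is.null(out)) utils::write.csv(compounds, out, row.names = FALSE)
  compounds
}
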