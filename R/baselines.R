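# Compared-method scoring: dual-encoder similarity and NLI-label-mapped
# criterion predictions, behind abstract encoder contracts.  No pretrained
# checkpoints are bundled; the default encoders are deterministic hashed
# projections so the scoring math is exercisable in tests.

#' Deterministic hashed text encoder
#'
#' Default implementation of the text-to-vector encoder contract: hashed
#' token counts in `dim` dimensions, optionally L2-normalized.  A test
#' double, not a trained model.
#'
#' @param dim Vector dimension `h`.
#' @param normalize L2-normalize the output (cosine geometry).
#' @return `function(text)` returning a numeric vector of length `dim`.
#' @export
hashed_encoder <- function(dim = 128L, normalize = FALSE) {
  function(text) {
    v <- numeric(dim)
    for (tok in .tokenize(text)) {
      j <- as.integer(.hash_string(tok) %% dim) + 1L
      v[j] <- v[j] + 1
    }
    if (normalize) {
      nrm <- sqrt(sum(v^2))
      if (nrm > 0) v <- v / nrm
    }
    v
  }
}

#' Dual-encoder ranking and excluding scores
#'
#' With a patient vector v and criterion vectors for the M inclusion and N
#' exclusion criteria:
#'   ranking  = mean_x v . V(i_x)  -  mean_y v . V(e_y)
#'   excluding =                      mean_y v . V(e_y)
#' An empty criterion side contributes 0 (the mean over zero terms is
#' defined as 0).  Dot products are raw by default; pass vectors from
#' `hashed_encoder(normalize = TRUE)` for the cosine variant.
#'
#' @param patient_vec Numeric patient encoding.
#' @param inclusion_vecs,exclusion_vecs Lists of criterion encodings (or
#'   matrices with one row per criterion); all vectors must share the
#'   patient vector's dimension.
#' @return A list with `ranking_score` and `excluding_score`.
#' @export
dual_encoder_scores <- function(patient_vec, inclusion_vecs, exclusion_vecs) {
  as_mat <- function(x) {
    if (is.null(x) || (is.list(x) && length(x) == 0L)) return(NULL)
    if (is.matrix(x)) return(x)
    do.call(rbind, x)
  }
  side_mean <- function(mat) {
    if (is.null(mat) || nrow(mat) == 0L) return(0)
    if (ncol(mat) != length(patient_vec)) .stopf("encoder dimension mismatch")
    mean(as.numeric(mat %*% patient_vec))
  }
  inc <- side_mean(as_mat(inclusion_vecs))
  exc <- side_mean(as_mat(exclusion_vecs))
  list(ranking_score = inc - exc, excluding_score = exc)
}

#' Map an NLI label to a criterion eligibility label
#'
#' Inclusion side: entailment -> included, contradiction -> not included,
#' neutral -> not enough information.  Exclusion side: entailment ->
#' excluded, contradiction -> not excluded, neutral -> not enough
#' information.  "not applicable" is unreachable from NLI labels.
#'
#' @param l One of `entailment`, `contradiction`, `neutral`.
#' @param side `"inclusion"` or `"exclusion"`.
#' @return The mapped eligibility label string.
#' @export
map_nli_label <- function(l, side = c("inclusion", "exclusion")) {
  side <- match.arg(side)
  if (!.is_string(l) || !l %in% c("entailment", "contradiction", "neutral")) {
    .stopf("unknown NLI label: %s", if (.is_string(l)) l else "<non-string>")
  }
  if (side == "inclusion") {
    switch(l,
      entailment = "included",
      contradiction = "not included",
      neutral = "not enough information"
    )
  } else {
    switch(l,
      entailment = "excluded",
      contradiction = "not excluded",
      neutral = "not enough information"
    )
  }
}

#' Baseline combination scores from linear percentage features
#'
#' For criterion labels from any source (NLI-mapped or otherwise):
#'   ranking   = pct_met_inclusion - pct_unmet_inclusion
#'             - pct_met_exclusion + pct_unmet_exclusion
#'   excluding = I(pct_unmet_inclusion > 0) + I(pct_met_exclusion > 0)
#'             - pct_met_inclusion
#'
#' @param linear A [linear_aggregate()] result.
#' @return A list with `ranking_score` and `excluding_score`.
#' @export
baseline_combination <- function(linear) {
  list(
    ranking_score = linear$pct_met_inclusion - linear$pct_unmet_inclusion -
      linear$pct_met_exclusion + linear$pct_unmet_exclusion,
    excluding_score = as.numeric(linear$pct_unmet_inclusion > 0) +
      as.numeric(linear$pct_met_exclusion > 0) -
      linear$pct_met_inclusion
  )
}
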