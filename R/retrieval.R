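# First-stage retrieval: keyword generation through the backend, per-keyword
# lexical (BM25) and dense retrieval, and decaying reciprocal-rank fusion.
#
# Fusion score for trial t over retrievers Ret and importance-ordered
# keywords w_1..w_K:
#
#   s_t = sum_Ret sum_{i=1..K} 1 / ( i * (Rank(Ret, w_i, t) + C) )
#
# with C = 20 by default; a (retriever, keyword) term contributes 0 when the
# trial is absent from that ranking, so scores do not depend on the
# configured retrieval depth.

#' Deterministic hashed bag-of-words dense retriever
#'
#' Default implementation of the dense-retriever contract: texts are
#' embedded as hashed token-count vectors and scored by cosine similarity.
#' It exercises the hybrid retrieval path deterministically without model
#' weights; it is not a trained semantic encoder.
#'
#' @param dim Embedding dimensionality.
#' @return A list with fields `id` and `score(query_text, doc_texts)`.
#' @export
hashed_cosine_retriever <- function(dim = 256L) {
  embed <- function(text) {
    v <- numeric(dim)
    for (tok in .tokenize(text)) {
      j <- as.integer(.hash_string(tok) %% dim) + 1L
      v[j] <- v[j] + 1
    }
    v
  }
  list(
    id = "dense",
    embed = embed,
    score = function(query_text, doc_vectors) {
      q <- embed(query_text)
      qn <- sqrt(sum(q^2))
      if (qn == 0) return(numeric(nrow(doc_vectors)))
      s <- as.numeric(doc_vectors %*% q)
      dn <- sqrt(rowSums(doc_vectors^2))
      ifelse(dn > 0, s / (dn * qn), 0)
    }
  )
}

#' Index a trial corpus for retrieval
#'
#' Each trial's document text is the concatenation of its title,
#' conditions, interventions, brief summary, and criteria.  Tokenization is
#' lowercase with splits on non-alphanumeric characters.  The lexical
#' retriever is BM25 (k1 = 1.5, b = 0.75, non-negative
#' log(1 + (N - df + 0.5)/(df + 0.5)) inverse document frequency); the
#' dense retriever is a pluggable contract, by default
#' [hashed_cosine_retriever()].
#'
#' @param trials List of [trial_record()] objects.
#' @param k1,b BM25 parameters.
#' @param dense Dense retriever contract, or `NULL` to index BM25 only.
#' @return A `trial_index` object.
#' @export
build_trial_index <- function(trials, k1 = 1.5, b = 0.75,
                              dense = hashed_cosine_retriever()) {
  if (length(trials) == 0L) .stopf("cannot index an empty corpus")
  ids <- vapply(trials, function(t) t$trial_id, character(1))
  if (anyDuplicated(ids)) .stopf("duplicate trial_id in corpus")
  docs <- vapply(trials, function(t) {
    paste(
      t$background$brief_title,
      paste(t$background$conditions, collapse = " "),
      paste(t$background$interventions, collapse = " "),
      t$background$brief_summary,
      paste(t$inclusion_criteria, collapse = " "),
      paste(t$exclusion_criteria, collapse = " ")
    )
  }, character(1))
  toks <- lapply(docs, .tokenize)
  tf <- lapply(toks, function(tk) {
    if (length(tk) == 0L) return(integer(0))
    table(tk)
  })
  doc_len <- vapply(toks, length, integer(1))
  df <- table(unlist(lapply(toks, unique)))
  dense_vectors <- NULL
  if (!is.null(dense)) {
    dense_vectors <- do.call(rbind, lapply(docs, dense$embed))
  }
  structure(
    list(
      trial_ids = ids, docs = docs, tf = tf, df = df,
      doc_len = doc_len, avgdl = mean(doc_len), n_docs = length(ids),
      k1 = k1, b = b, dense = dense, dense_vectors = dense_vectors
    ),
    class = "trial_index"
  )
}

# BM25 scores of every indexed document for one query string.
.bm25_scores <- function(index, query) {
  qtoks <- unique(.tokenize(query))
  scores <- numeric(index$n_docs)
  for (term in qtoks) {
    dfi <- index$df[term]
    if (is.na(dfi)) next
    idf <- log(1 + (index$n_docs - dfi + 0.5) / (dfi + 0.5))
    for (d in seq_len(index$n_docs)) {
      f <- index$tf[[d]][term]
      if (is.na(f)) next
      f <- as.numeric(f)
      norm <- index$k1 * (1 - index$b + index$b * index$doc_len[d] / index$avgdl)
      scores[d] <- scores[d] + idf * f * (index$k1 + 1) / (f + norm)
    }
  }
  scores
}

#' Rank trials for one keyword with one retriever
#'
#' Returns the top `depth` trials with strictly positive retriever score,
#' ordered by descending score with ties broken by ascending trial ID.  A
#' keyword matching no trial yields an empty ranking.
#'
#' @param keyword Query keyword.
#' @param retriever `"bm25"` or `"dense"`.
#' @param index A [build_trial_index()] object.
#' @param depth Maximum number of trials returned.
#' @return A data.frame with columns `retriever_id`, `keyword`,
#'   `trial_id`, `rank`, `score`.
#' @export
rank_for_keyword <- function(keyword, retriever = c("bm25", "dense"), index,
                             depth = 1000L) {
  retriever <- match.arg(retriever)
  if (!inherits(index, "trial_index")) .stopf("corpus is not indexed; call build_trial_index()")
  if (!.is_count(depth) || depth < 1) .stopf("depth must be a positive integer")
  scores <- if (retriever == "bm25") {
    .bm25_scores(index, keyword)
  } else {
    if (is.null(index$dense)) .stopf("index was built without a dense retriever")
    index$dense$score(keyword, index$dense_vectors)
  }
  keep <- which(scores > 0)
  ord <- keep[order(-scores[keep], index$trial_ids[keep])]
  ord <- utils::head(ord, depth)
  data.frame(
    retriever_id = rep(retriever, length(ord)),
    keyword = rep(keyword, length(ord)),
    trial_id = index$trial_ids[ord],
    rank = seq_along(ord),
    score = scores[ord],
    stringsAsFactors = FALSE
  )
}

#' Fuse per-keyword rankings with decaying reciprocal rank
#'
#' @param rankings A list of per-(retriever, keyword) rankings as returned
#'   by [rank_for_keyword()], each tagged with its 1-based keyword
#'   importance index via the `keyword_index` attribute, or a single
#'   data.frame with an extra `keyword_index` column.
#' @param C Reciprocal-rank-fusion constant, default 20; must be positive.
#' @return A data.frame (`trial_id`, `score`) sorted by descending score,
#'   ties by ascending trial ID; trials absent from every ranking are
#'   excluded (their score is 0).
#' @export
fuse_rankings <- function(rankings, C = 20) {
  if (!is.numeric(C) || length(C) != 1L || C <= 0) .stopf("C must be a positive number")
  if (is.data.frame(rankings)) {
    if (is.null(rankings$keyword_index)) .stopf("rankings data.frame needs a keyword_index column")
    df <- rankings
  } else {
    if (length(rankings) == 0L) .stopf("empty keyword set")
    df <- do.call(rbind, lapply(rankings, function(r) {
      ki <- attr(r, "keyword_index")
      if (is.null(ki)) .stopf("each ranking needs a keyword_index attribute")
      if (nrow(r) == 0L) return(NULL)
      cbind(r, keyword_index = as.integer(ki))
    }))
  }
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(trial_id = character(0), score = numeric(0), stringsAsFactors = FALSE))
  }
  contrib <- 1 / (df$keyword_index * (df$rank + C))
  agg <- tapply(contrib, df$trial_id, sum)
  out <- data.frame(trial_id = names(agg), score = as.numeric(agg), stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$trial_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.keyword_prompt <- function(patient, max_keywords) {
  paste0(
    "You are helping to find clinical trials for a patient.\n",
    "Read the patient description below and list up to ", max_keywords,
    " medical keywords or phrases describing the patient's conditions,\n",
    "ranked from most to least important.  Respond with a JSON array of strings.\n\n",
    "Patient description:\n", patient$raw_text, "\n"
  )
}

#' Generate importance-ranked keywords for a patient
#'
#' The backend is asked for a JSON array of keywords ranked by importance.
#' The returned list is deduplicated case-insensitively (first occurrence
#' wins) and truncated to `max_keywords`; position in the list is the
#' importance rank used by [fuse_rankings()].
#'
#' @param patient A [patient_note()].
#' @param backend A backend (see [make_backend()]).
#' @param max_keywords Maximum number of keywords kept (default 32).
#' @return A `keyword_list`: list with `patient_id` and `keywords`.
#' @export
generate_keywords <- function(patient, backend, max_keywords = 32L) {
  if (!.is_count(max_keywords) || max_keywords < 1) .stopf("max_keywords must be >= 1")
  req <- backend_request(
    "keywords", .keyword_prompt(patient, max_keywords),
    meta = list(patient_id = patient$patient_id)
  )
  resp <- complete(backend, req)
  kws <- tryCatch(
    unlist(jsonlite::fromJSON(resp$raw_text, simplifyVector = TRUE)),
    error = function(e) .stopf("keyword response is not valid JSON: %s", conditionMessage(e))
  )
  kws <- as.character(kws)
  kws <- kws[nzchar(trimws(kws))]
  kws <- kws[!duplicated(tolower(kws))]
  kws <- utils::head(kws, max_keywords)
  if (length(kws) == 0L) .stopf("backend returned zero keywords for patient %s", patient$patient_id)
  structure(list(patient_id = patient$patient_id, keywords = kws), class = "keyword_list")
}

#' Retrieve candidate trials for a patient
#'
#' Composition of [generate_keywords()], [rank_for_keyword()] per
#' (retriever, keyword), and [fuse_rankings()], truncated to `top_k`.
#'
#' @param patient A [patient_note()].
#' @param index A [build_trial_index()] object.
#' @param backend Keyword-generation backend.
#' @param top_k Number of candidates kept (default 500).
#' @param C Fusion constant.
#' @param max_keywords Passed to [generate_keywords()].
#' @param depth Per-keyword retrieval depth.
#' @return A [run_list()] for this patient.
#' @export
retrieve_candidates <- function(patient, index, backend, top_k = 500L, C = 20,
                                max_keywords = 32L, depth = 1000L) {
  kl <- generate_keywords(patient, backend, max_keywords = max_keywords)
  retrievers <- c("bm25", if (!is.null(index$dense)) "dense")
  rankings <- list()
  for (ret in retrievers) {
    for (i in seq_along(kl$keywords)) {
      r <- rank_for_keyword(kl$keywords[i], ret, index, depth = depth)
      attr(r, "keyword_index") <- i
      rankings[[length(rankings) + 1L]] <- r
    }
  }
  fused <- fuse_rankings(rankings, C = C)
  fused <- utils::head(fused, top_k)
  run_list(rep(patient$patient_id, nrow(fused)), fused$trial_id, fused$score)
}
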