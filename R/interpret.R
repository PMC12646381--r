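# Attention-based attribution for target predictions and code-embedding
# export for 2-D projection. "Attention" here is the causal self-attention
# of the final layer from the predicting position, averaged across heads
# (decoder-only models have no encoder-decoder cross-attention).

#' Most-attended input tokens at a target-predicting step
#'
#' At `step` (default: the last prefix position) the model's top-1 forecast
#' must equal `target`; the attention weights from that position over all
#' prior positions — final layer, averaged across heads — are ranked and
#' the top `k` input positions returned, ties broken by earlier position.
#' Structural and demographic tokens are eligible (age, for example, can be
#' reported).
#'
#' @param model a fitted `ehr_lm`.
#' @param prefix input sequence (ids or `ehr_sequence`).
#' @param target token id (or token string) that must be the top-1 forecast.
#' @param step prefix position at which the prediction is made; defaults to
#'   the full prefix length.
#' @param k number of attended positions to return, default 15.
#' @return data frame with `position`, `token`, `weight`, ordered by
#'   decreasing weight.
#' @export
attended_tokens <- function(model, prefix, target, step = NULL, k = 15L) {
  stopifnot(inherits(model, "ehr_lm"))
  ids <- .as_prefix_ids(model, prefix)
  if (is.character(target)) target <- model$vocab$token_to_id[[target]]
  if (is.null(target) || is.na(target)) stop("unknown target token", call. = FALSE)
  step <- step %||% length(ids)
  if (step < 1L || step > length(ids)) stop("step outside the prefix", call. = FALSE)
  ids <- ids[seq_len(step)]

  fwd <- .lm_forward(model$par, model$config, ids, length(ids), want = "attn")
  p <- fwd$logits[length(ids), ]
  top1 <- order(-p, seq_along(p))[1L]
  if (top1 != target) {
    stop(sprintf("top-1 forecast at step %d is '%s', not the target '%s'",
                 step, model$vocab$tokens[top1], model$vocab$tokens[target]),
         call. = FALSE)
  }
  w <- colMeans(fwd$attn_last[[1L]])  # head-averaged final-layer attention row
  k <- min(k, length(w))
  ord <- order(-w, seq_along(w))[seq_len(k)]
  data.frame(position = ord, token = model$vocab$tokens[ids[ord]],
             weight = w[ord], row.names = NULL)
}

#' Aggregate attended codes across a cohort
#'
#' Counts each code once per patient in whose top-k attended list it
#' appears, returns the `top` most frequent with max-normalized frequencies
#' (1 = the most frequent code). Codes tied with the code at rank `top` are
#' all included, with a flag.
#'
#' @param attended_lists list (one element per patient) of data frames from
#'   [attended_tokens()] or character vectors of attended tokens.
#' @param top number of codes to report, default 10.
#' @return an `ehr_attention_summary`: data frame `token`, `count`,
#'   `frequency` (max-normalized), plus attributes `n_patients` and
#'   `ties_at_cutoff`.
#' @export
aggregate_attention <- function(attended_lists, top = 10L) {
  if (!length(attended_lists)) stop("no attended-token lists supplied", call. = FALSE)
  per_patient <- lapply(attended_lists, function(x) {
    toks <- if (is.data.frame(x)) x$token else as.character(x)
    unique(toks)
  })
  tab <- sort(table(unlist(per_patient, use.names = FALSE)), decreasing = TRUE)
  counts <- as.integer(tab)
  tokens <- names(tab)
  ties <- FALSE
  if (length(counts) > top) {
    cutoff <- counts[top]
    keep <- counts >= cutoff
    ties <- sum(counts == cutoff) > 1L && sum(keep) > top
  } else {
    keep <- rep(TRUE, length(counts))
  }
  df <- data.frame(token = tokens[keep], count = counts[keep],
                   frequency = counts[keep] / max(counts),
                   row.names = NULL)
  structure(df, class = c("ehr_attention_summary", "data.frame"),
            n_patients = length(attended_lists), ties_at_cutoff = ties)
}

# the 14 higher-level ICD-10 chapter ranges used for category-level tasks
.ICD10_CHAPTERS <- data.frame(
  start = c("A00", "C00", "D50", "E00", "F01", "G00", "H00", "H60", "I00",
            "J00", "K00", "L00", "M00", "N00"),
  end = c("B99", "D49", "D89", "E89", "F99", "G99", "H59", "H95", "I99",
          "J99", "K95", "L99", "M99", "N99"),
  label = c("A00-B99 infectious and parasitic",
            "C00-D49 neoplasms",
            "D50-D89 blood and immune",
            "E00-E89 endocrine, nutritional and metabolic",
            "F01-F99 mental and behavioural",
            "G00-G99 nervous system",
            "H00-H59 eye and adnexa",
            "H60-H95 ear and mastoid",
            "I00-I99 circulatory system",
            "J00-J99 respiratory system",
            "K00-K95 digestive system",
            "L00-L99 skin and subcutaneous tissue",
            "M00-M99 musculoskeletal and connective tissue",
            "N00-N99 genitourinary system"),
  stringsAsFactors = FALSE)

#' The 14 higher-level ICD-10 chapter ranges
#'
#' @return data frame with `start`, `end` and `label` for each chapter.
#' @export
icd10_chapters <- function() .ICD10_CHAPTERS

#' The 12 specific diagnostic target conditions
#'
#' Condition groups used for the zero-shot diagnostic tasks; each element
#' is a vector of grouped ICD-10 codes.
#'
#' @return named list of character vectors.
#' @export
zero_shot_targets <- function() {
  list(depression = c("F32", "F33", "F34"),
       heart_failure = "I50",
       end_stage_renal_disease = "N18",
       chronic_ischemic_heart_disease = "I25",
       type_2_diabetes = "E11",
       copd = "J44",
       pancreatic_cancer = "C25",
       liver_cancer = "C22",
       brain_cancer = "C71",
       cerebral_infarction = "I63",
       rheumatoid_arthritis = "M06",
       systemic_lupus_erythematosus = "M32")
}

.chapter_of <- function(codes) {
  ch <- .ICD10_CHAPTERS
  out <- rep(NA_character_, length(codes))
  for (i in seq_len(nrow(ch))) {
    hit <- codes >= ch$start[i] & codes <= ch$end[i]
    out[hit & is.na(out)] <- ch$label[i]
  }
  out
}

#' Export learned diagnosis-code embeddings for 2-D projection
#'
#' One row per retained diagnosis code inside the requested chapter ranges:
#' the code, its chapter label, and the input-embedding vector. The
#' delimited output feeds any projection tool (for example UMAP via the
#' bundled CLI, which delegates to an established implementation); the
#' projection itself is not part of the package.
#'
#' @param model a fitted `ehr_lm`.
#' @param chapters `"all"` for the 14 chapter ranges, or a character vector
#'   of ranges such as `"C00-D49"`.
#' @param file optional path; when given, the matrix is written as
#'   tab-separated text.
#' @return (invisibly, when `file` is given) a data frame with `code`,
#'   `chapter`, and embedding columns `e1..ed`.
#' @export
export_code_embeddings <- function(model, chapters = "all", file = NULL) {
  stopifnot(inherits(model, "ehr_lm"))
  vocab <- model$vocab
  dx_tokens <- vocab$tokens[startsWith(vocab$tokens, "DX:")]
  codes <- sub("^DX:", "", dx_tokens)
  chap <- .chapter_of(codes)
  if (!identical(chapters, "all")) {
    sel <- rep(FALSE, length(codes))
    for (r in chapters) {
      lim <- strsplit(toupper(r), "-", fixed = TRUE)[[1]]
      if (length(lim) != 2L) stop(sprintf("bad chapter range '%s'", r), call. = FALSE)
      sel <- sel | (codes >= lim[1] & codes <= lim[2])
    }
  } else {
    sel <- !is.na(chap)
  }
  if (!any(sel)) stop("no diagnosis codes match the chapter filter", call. = FALSE)
  ids <- unname(vocab$token_to_id[dx_tokens[sel]])
  emb <- model$par$tok[ids, , drop = FALSE]
  colnames(emb) <- paste0("e", seq_len(ncol(emb)))
  out <- cbind(data.frame(code = codes[sel], chapter = chap[sel],
                          stringsAsFactors = FALSE),
               as.data.frame(emb))
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
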