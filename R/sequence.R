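# Linearization of a patient record into the token grammar:
#   [SEX, AGE, V1, SEP, t, V2, SEP, ...]
# with a relative-time token opening every visit except the first, a
# visit-type token, events ordered deterministically, an optional
# discharge-type token, and SEP terminating each visit block.

#' Relative-time token for an inter-visit gap
#'
#' Maps the gap (days) since the previous visit to one of four tokens:
#' `T0` within the same quarter (<= 91 days), `T1` more than 3 but within 6
#' months (92-182), `T2` more than 6 months but within a year (183-365),
#' `T3` more than a year (> 365). The four ranges partition the non-negative
#' integers.
#'
#' @param gap_days non-negative integer vector of gaps in days.
#' @return character vector of time tokens.
#' @examples
#' assign_time_token(c(0, 91, 92, 182, 183, 365, 366))
#' @export
assign_time_token <- function(gap_days) {
  if (!is.numeric(gap_days) || anyNA(gap_days) || any(gap_days < 0)) {
    stop("gap_days must be non-negative", call. = FALSE)
  }
  c("T0", "T1", "T2", "T3")[findInterval(gap_days, c(0, 92, 183, 366))]
}

# simulated days attributed to each generated time token inside the
# prediction window: the midpoint of its range (T3: one midpoint beyond a year)
.TIME_TOKEN_MIDPOINT_DAYS <- c(T0 = 45, T1 = 137, T2 = 274, T3 = 548)

.age_bucket_token <- function(birth_date, at_date) {
  age <- floor(as.numeric(at_date - birth_date) / 365.25)
  bucket <- max(0L, min(115L, (as.integer(age) %/% .AGE_BUCKET_WIDTH) * .AGE_BUCKET_WIDTH))
  sprintf("AGE:%03d", bucket)
}

# tokens of one visit (without SEP); events ordered by timestamp, then fixed
# domain order (diagnosis, procedure, medication, lab), then code
.visit_tokens <- function(visit, vocab, mapping) {
  ev <- visit$events
  out <- paste0("VT:", visit$visit_type)
  n_dropped <- 0L
  if (nrow(ev)) {
    ord <- order(match(ev$domain, c("diagnosis", "procedure", "medication", "lab")),
                 ev$code)
    ev <- ev[ord, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      d <- ev$domain[i]
      code <- .normalize_domain_codes(ev$code[i], d, mapping)
      tok <- if (d == "lab") {
        if (is.null(vocab$lab_deciles[[code]])) NA_character_
        else discretize_lab(code, ev$value[i], vocab)
      } else {
        paste0(.domain_prefix[[d]], code)
      }
      if (!is.na(tok) && tok %in% names(vocab$token_to_id)) {
        out <- c(out, tok)
      } else {
        n_dropped <- n_dropped + 1L
      }
    }
  }
  if (!is.na(visit$discharge)) {
    dtok <- paste0("DT:", visit$discharge)
    if (dtok %in% names(vocab$token_to_id)) out <- c(out, dtok)
  }
  out <- out[out %in% names(vocab$token_to_id)]
  list(tokens = out, n_dropped = n_dropped)
}

#' Linearize a patient record into a token sequence
#'
#' Emits the demographics prefix (sex token, 5-year age bucket at first
#' visit) followed by one block per visit; every visit except the first
#' opens with a relative-time token, and every block ends with SEP. Events
#' are ordered by timestamp, then fixed domain order (diagnosis, procedure,
#' medication, lab), then code, for deterministic training sequences. Codes
#' absent from the vocabulary are dropped and counted. If the sequence
#' exceeds `max_len`, whole oldest visit blocks are dropped (the demographics
#' prefix is always kept and the retained suffix's first visit loses its
#' time token) until it fits.
#'
#' @param record an `ehr_record`.
#' @param vocab an `ehr_vocab`.
#' @param mapping optional `ehr_code_mapping`, applied as during vocabulary
#'   construction.
#' @param max_len context window, default 512 tokens.
#' @return an `ehr_sequence`: `person_id`, integer `token_ids`,
#'   `visit_index` (0 for the demographics prefix), `visit_dates` of the
#'   retained visits, and the dropped-token count `n_dropped`.
#' @export
build_sequence <- function(record, vocab, mapping = NULL, max_len = 512L) {
  stopifnot(inherits(vocab, "ehr_vocab"))
  if (!length(record$visits)) stop("record has no visits", call. = FALSE)
  n_visits <- length(record$visits)
  dates <- do.call(c, lapply(record$visits, function(v) v$date))

  prefix <- c(paste0("SEX:", record$sex),
              .age_bucket_token(record$birth_date, dates[1]))
  prefix <- prefix[prefix %in% names(vocab$token_to_id)]

  vis <- lapply(record$visits, .visit_tokens, vocab = vocab, mapping = mapping)
  n_dropped <- sum(vapply(vis, function(v) v$n_dropped, integer(1)))
  blocks <- lapply(vis, function(v) v$tokens)
  n_events <- sum(vapply(blocks, function(b) sum(.is_event_token(b)), integer(1)))
  if (n_events == 0L) {
    stop(sprintf("record %s has no mappable events", record$person_id), call. = FALSE)
  }
  gaps <- as.numeric(diff(dates))
  time_tok <- c(NA_character_, assign_time_token(pmax(gaps, 0)))

  # length with visits start..n_visits retained (first retained has no time token)
  block_len <- lengths(blocks) + 1L                    # + SEP
  len_from <- function(start) {
    idx <- start:n_visits
    length(prefix) + sum(block_len[idx]) + (length(idx) - 1L)  # time tokens
  }
  start <- 1L
  while (start < n_visits && len_from(start) > max_len) start <- start + 1L

  tokens <- prefix
  visit_index <- rep(0L, length(prefix))
  for (v in start:n_visits) {
    blk <- c(if (v > start) time_tok[v], blocks[[v]], "SEP")
    tokens <- c(tokens, blk)
    visit_index <- c(visit_index, rep(v - start + 1L, length(blk)))
  }
  if (length(tokens) > max_len) {
    warning(sprintf("single visit of record %s exceeds max_len; truncating its events",
                    record$person_id), call. = FALSE)
    keep <- c(seq_len(max_len - 1L), length(tokens))  # keep final SEP
    tokens <- tokens[keep]
    visit_index <- visit_index[keep]
  }

  structure(
    list(person_id = record$person_id,
         token_ids = unname(vocab$token_to_id[tokens]),
         visit_index = visit_index,
         visit_dates = dates[start:n_visits],
         n_dropped = n_dropped),
    class = "ehr_sequence")
}

#' @export
print.ehr_sequence <- function(x, ...) {
  cat(sprintf("EHR token sequence: person %s, %d tokens, %d visits\n",
              x$person_id, length(x$token_ids), max(x$visit_index)))
  invisible(x)
}

#' Decode a token sequence back into visit structures
#'
#' Splits on SEP and classifies structural versus event tokens. On
#' untruncated records, `decode_sequence(build_sequence(r))` recovers the
#' visit structure exactly. A time token anywhere other than the first
#' position of a (non-first) visit block raises a structural error naming
#' the offending position.
#'
#' @param x an `ehr_sequence`, or an integer vector of token ids.
#' @param vocab the `ehr_vocab` the ids refer to.
#' @return a list with `sex`, `age_token`, and `visits`: per visit a list
#'   with `time_token` (NA for the first visit), `visit_type`, `discharge`
#'   and the character vector `events`.
#' @export
decode_sequence <- function(x, vocab) {
  ids <- if (inherits(x, "ehr_sequence")) x$token_ids else as.integer(x)
  toks <- decode_tokens(vocab, ids)
  if (anyNA(toks)) stop("sequence contains ids outside the vocabulary", call. = FALSE)

  pos <- 1L
  sex <- NA_character_; age <- NA_character_
  while (pos <= length(toks) && grepl("^(SEX|AGE):", toks[pos])) {
    if (startsWith(toks[pos], "SEX:")) sex <- sub("^SEX:", "", toks[pos])
    if (startsWith(toks[pos], "AGE:")) age <- toks[pos]
    pos <- pos + 1L
  }

  visits <- list()
  block <- character(0); block_pos <- integer(0)
  first_block <- TRUE
  finish_block <- function(block, block_pos, first_block) {
    if (!length(block)) return(NULL)
    time_token <- NA_character_
    i <- 1L
    if (.is_time_token(block[1L])) {
      time_token <- block[1L]
      i <- 2L
    }
    rest <- block[seq.int(i, length.out = length(block) - i + 1L)]
    rest_pos <- block_pos[seq.int(i, length.out = length(block) - i + 1L)]
    bad <- which(.is_time_token(rest))
    if (length(bad)) {
      stop(sprintf("structural error: time token inside a visit at position %d",
                   rest_pos[bad[1L]]), call. = FALSE)
    }
    vt <- NA_character_; dt <- NA_character_
    is_vt <- startsWith(rest, "VT:"); is_dt <- startsWith(rest, "DT:")
    if (any(is_vt)) vt <- sub("^VT:", "", rest[which(is_vt)[1L]])
    if (any(is_dt)) dt <- sub("^DT:", "", rest[which(is_dt)[1L]])
    list(time_token = time_token, visit_type = vt, discharge = dt,
         events = rest[!is_vt & !is_dt & rest != "PAD"])
  }
  for (p in seq.int(pos, length.out = length(toks) - pos + 1L)) {
    tok <- toks[p]
    if (tok == "SEP") {
      vb <- finish_block(block, block_pos, first_block)
      if (!is.null(vb)) { visits[[length(visits) + 1L]] <- vb; first_block <- FALSE }
      block <- character(0); block_pos <- integer(0)
    } else {
      block <- c(block, tok); block_pos <- c(block_pos, p)
    }
  }
  vb <- finish_block(block, block_pos, first_block)
  if (!is.null(vb)) visits[[length(visits) + 1L]] <- vb

  list(sex = sex, age_token = age, visits = visits)
}

#' Tokenize a whole cohort
#'
#' Applies [build_sequence()] to every record; records with no mappable
#' events are skipped with a message reporting the count.
#'
#' @inheritParams build_sequence
#' @param records an `ehr_cohort` / list of `ehr_record`.
#' @return list of `ehr_sequence`.
#' @export
tokenize_cohort <- function(records, vocab, mapping = NULL, max_len = 512L) {
  out <- list(); skipped <- 0L
  for (r in records) {
    s <- tryCatch(build_sequence(r, vocab, mapping, max_len),
                  error = function(e) NULL)
    if (is.null(s)) skipped <- skipped + 1L else out[[length(out) + 1L]] <- s
  }
  if (skipped > 0L) message(sprintf("skipped %d record(s) with no mappable events", skipped))
  out
}

#' Write a tokenized corpus (and read it back)
#'
#' One record per line: the person id followed by space-separated token ids.
#' A JSON sidecar (`<path>.meta.json`) stores per-record visit dates and
#' dropped-token counts so sequences round-trip exactly.
#'
#' @param sequences list of `ehr_sequence`.
#' @param path corpus file path.
#' @return `write_corpus`: invisibly, `path`; `read_corpus`: the list of
#'   `ehr_sequence`.
#' @export
write_corpus <- function(sequences, path) {
  lines <- vapply(sequences, function(s) {
    paste(c(as.character(s$person_id), s$token_ids), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  meta <- lapply(sequences, function(s) {
    list(person_id = s$person_id,
         visit_dates = format(s$visit_dates),
         n_dropped = s$n_dropped)
  })
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_corpus
#' @param vocab the `ehr_vocab` used to tokenize the corpus.
#' @export
read_corpus <- function(path, vocab) {
  lines <- readLines(path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = FALSE)
  } else NULL
  lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    ids <- as.integer(parts[-1])
    m <- if (!is.null(meta)) meta[[i]] else NULL
    structure(
      list(person_id = parts[1],
           token_ids = ids,
           visit_index = .visit_index_from_ids(ids, vocab),
           visit_dates = if (!is.null(m)) as.Date(unlist(m$visit_dates)) else NULL,
           n_dropped = if (!is.null(m)) m$n_dropped else NA_integer_),
      class = "ehr_sequence")
  })
}

# visit index (0 = demographics prefix) recomputed from the token stream
.visit_index_from_ids <- function(ids, vocab) {
  toks <- decode_tokens(vocab, ids)
  n <- length(toks)
  vi <- integer(n)
  cur <- 0L
  in_prefix <- TRUE
  sep_id_seen <- FALSE
  for (p in seq_len(n)) {
    if (in_prefix && grepl("^(SEX|AGE):", toks[p])) {
      vi[p] <- 0L
      next
    }
    if (in_prefix) { in_prefix <- FALSE; cur <- 1L }
    vi[p] <- cur
    if (toks[p] == "SEP") cur <- cur + 1L
  }
  vi
}
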