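# Token vocabulary: code normalization, GEM-style code mapping, rare-code
# filtering, per-lab eCDF decile boundaries, and the token<->id registry.

# fixed structural tokens, always first and in this order
.STRUCTURAL_TOKENS <- c("PAD", "SEP", "T0", "T1", "T2", "T3")
.TIME_TOKENS <- c("T0", "T1", "T2", "T3")
.AGE_BUCKET_WIDTH <- 5L
.AGE_TOKENS <- sprintf("AGE:%03d", seq(0L, 115L, by = 5L))
.SEX_TOKENS <- c("SEX:F", "SEX:M")

.domain_prefix <- c(diagnosis = "DX:", medication = "RX:",
                    procedure = "PX:", lab = "LAB:")

#' Group a diagnosis code to its 3-character stem
#'
#' Reduces a full ICD-10 code to the (at most) three characters before the
#' decimal point, uppercased, shrinking the diagnosis vocabulary
#' (`"E11.9" -> "E11"`).
#'
#' @param code character vector of diagnosis codes.
#' @return character vector of grouped codes.
#' @examples
#' normalize_diagnosis_code(c("E11.9", "I50", "c25.0"))
#' @export
normalize_diagnosis_code <- function(code) {
  if (!is.character(code) || length(code) == 0L || anyNA(code) || any(!nzchar(code))) {
    stop("diagnosis codes must be non-empty strings", call. = FALSE)
  }
  stem <- sub("\\..*$", "", code)
  toupper(substr(stem, 1L, 3L))
}

#' Load a two-column code mapping table
#'
#' Reads a delimited text file whose first two columns are source code and
#' target code (for example an ICD-9 to ICD-10 General Equivalence Mapping
#' extract supplied by the user; no terminology content ships with the
#' package). Codes absent from the table map to themselves.
#'
#' @param path file path; delimiter is auto-detected among comma and tab.
#' @param header whether the file carries a header row.
#' @return an object of class `ehr_code_mapping`.
#' @export
read_code_mapping <- function(path, header = TRUE) {
  if (!file.exists(path)) stop(sprintf("mapping file '%s' not found", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = header,
                          colClasses = "character", quote = "\"")
  if (ncol(df) < 2L) stop("mapping file needs at least two columns", call. = FALSE)
  code_mapping(stats::setNames(df[[2L]], df[[1L]]))
}

#' Build a code mapping from a named vector
#'
#' @param map named character vector, `names(map)` the source codes and the
#'   values the target codes.
#' @return an object of class `ehr_code_mapping`.
#' @export
code_mapping <- function(map = character(0)) {
  if (length(map) && (is.null(names(map)) || any(!nzchar(names(map))))) {
    stop("mapping must be a named character vector", call. = FALSE)
  }
  structure(list(map = map), class = "ehr_code_mapping")
}

#' Apply a code mapping with identity fallback
#'
#' @param code character vector of codes.
#' @param mapping an `ehr_code_mapping`; `NULL` is treated as the identity.
#' @return character vector of mapped codes; codes absent from the table are
#'   returned unchanged.
#' @examples
#' m <- code_mapping(c("250.00" = "E11.9"))
#' apply_code_mapping(c("250.00", "401.9"), m)
#' @export
apply_code_mapping <- function(code, mapping = NULL) {
  if (is.null(mapping)) return(code)
  stopifnot(inherits(mapping, "ehr_code_mapping"))
  hit <- match(code, names(mapping$map))
  out <- code
  out[!is.na(hit)] <- unname(mapping$map[hit[!is.na(hit)]])
  out
}

# mapped + grouped code for one domain
.normalize_domain_codes <- function(codes, domain, mapping) {
  codes <- apply_code_mapping(codes, mapping)
  if (domain == "diagnosis") codes <- normalize_diagnosis_code(codes)
  codes
}

#' Count, per code, the number of distinct patients carrying it
#'
#' Each code counts at most once per patient, regardless of how many visits
#' repeat it; this makes the rare-code filter robust to repeat billing.
#' Diagnosis codes are mapped and grouped before counting.
#'
#' @param records an `ehr_cohort` / list of `ehr_record`.
#' @param mapping optional `ehr_code_mapping` applied before counting.
#' @return named integer vector: patient count per `domain:code` key, with a
#'   `domain` attribute vector parallel to it.
#' @export
compute_code_frequencies <- function(records, mapping = NULL) {
  if (!length(records)) stop("records must be non-empty", call. = FALSE)
  per_patient <- lapply(records, function(r) {
    keys <- character(0)
    for (v in r$visits) {
      ev <- v$events
      if (!nrow(ev)) next
      codes <- ev$code
      for (d in unique(ev$domain)) {
        i <- ev$domain == d
        codes[i] <- .normalize_domain_codes(ev$code[i], d, mapping)
      }
      keys <- c(keys, paste(ev$domain, codes, sep = "\r"))
    }
    unique(keys)
  })
  keys <- unlist(per_patient, use.names = FALSE)
  if (!length(keys)) return(stats::setNames(integer(0), character(0)))
  tab <- table(keys)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- as.integer(tab)
  names(out) <- vapply(parts, `[`, character(1), 2L)
  attr(out, "domain") <- vapply(parts, `[`, character(1), 1L)
  out
}

#' Retain codes carried by at least a fraction of patients
#'
#' Codes carried by strictly fewer than `threshold` of the patients are
#' removed; a code at exactly the threshold is retained.
#'
#' @param frequencies named patient counts, e.g. from
#'   [compute_code_frequencies()].
#' @param n_patients cohort size the fractions refer to.
#' @param threshold removal fraction, default 0.001 (0.1%).
#' @return the retained subset of `frequencies` (names and `domain`
#'   attribute preserved).
#' @export
filter_rare_codes <- function(frequencies, n_patients, threshold = 0.001) {
  .assert_count(n_patients, "n_patients")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    .stop_cfg("threshold", "must be in (0, 1)")
  }
  keep <- (frequencies / n_patients) >= threshold
  out <- frequencies[keep]
  dom <- attr(frequencies, "domain")
  if (!is.null(dom)) attr(out, "domain") <- dom[keep]
  out
}

#' Fit per-lab eCDF decile boundaries
#'
#' For each lab code, the nine boundaries are the empirical 10th..90th
#' percentiles of its training values under the left-continuous inverse of
#' the empirical CDF (type-1 quantiles), i.e. the sorted value at index
#' `ceiling(k * n / 10)`. Labs with fewer than `min_values` training values
#' are excluded with a warning; all-identical values yield degenerate (equal)
#' boundaries with a warning.
#'
#' @param lab_values named list: lab code -> numeric vector of training
#'   values (training split only).
#' @param min_values minimum number of training values per lab, default 10.
#' @return named list: lab code -> sorted numeric vector of 9 boundaries.
#' @export
fit_lab_deciles <- function(lab_values, min_values = 10L) {
  stopifnot(is.list(lab_values))
  out <- list()
  for (code in names(lab_values)) {
    x <- lab_values[[code]]
    x <- x[is.finite(x)]
    if (length(x) < min_values) {
      warning(sprintf("lab '%s' has %d < %d training values; excluded",
                      code, length(x), min_values), call. = FALSE)
      next
    }
    # left-continuous eCDF inverse: sorted value at index ceil(k*n/10),
    # computed in exact integer arithmetic
    n <- length(x)
    b <- sort(x)[((1:9) * n + 9L) %/% 10L]
    if (length(unique(x)) == 1L) {
      warning(sprintf("lab '%s' has all-identical training values; degenerate bins", code),
              call. = FALSE)
    }
    out[[code]] <- b
  }
  out
}

#' Discretize a lab value into its eCDF decile bin
#'
#' The bin is the number of fitted boundaries strictly below the value,
#' clipped to 0..9; out-of-range values at inference therefore fall in the
#' extreme bins rather than creating unseen tokens.
#'
#' @param lab_code lab code with fitted boundaries in `vocab`.
#' @param value numeric value(s).
#' @param vocab an `ehr_vocab` (or a plain list of boundary vectors).
#' @return the compound lab token(s), `"LAB:<code>:<bin>"`.
#' @export
discretize_lab <- function(lab_code, value, vocab) {
  deciles <- if (inherits(vocab, "ehr_vocab")) vocab$lab_deciles else vocab
  b <- deciles[[lab_code]]
  if (is.null(b)) stop(sprintf("unknown lab code '%s' (no fitted deciles)", lab_code),
                       call. = FALSE)
  bin <- vapply(value, function(v) sum(b < v), numeric(1))
  bin <- pmin(pmax(bin, 0), 9)
  sprintf("LAB:%s:%d", lab_code, as.integer(bin))
}

# low-level vocabulary constructor; tokens must already be unique
.new_vocab <- function(tokens, lab_deciles = list(), frequencies = integer(0),
                       threshold = NA_real_, n_patients = NA_integer_) {
  stopifnot(!anyDuplicated(tokens))
  structure(
    list(tokens = tokens,
         token_to_id = stats::setNames(seq_along(tokens), tokens),
         lab_deciles = lab_deciles,
         frequencies = frequencies,
         threshold = threshold,
         n_patients = n_patients,
         version = 1L),
    class = "ehr_vocab")
}

#' Construct a vocabulary from event tokens
#'
#' Lightweight constructor for hand-built vocabularies (simulation studies,
#' toy grammars). The structural tokens (PAD, SEP, T0-T3), sex and age-bucket
#' tokens are always included, in a fixed order, before the supplied event
#' tokens.
#'
#' @param event_tokens character vector of event tokens.
#' @param extra_special additional special tokens (e.g. visit-type tokens),
#'   placed after the fixed specials.
#' @param lab_deciles optional named list of fitted decile boundaries.
#' @return an `ehr_vocab`.
#' @export
ehr_vocabulary <- function(event_tokens = character(0),
                           extra_special = character(0),
                           lab_deciles = list()) {
  specials <- c(.STRUCTURAL_TOKENS, .SEX_TOKENS, .AGE_TOKENS, sort(unique(extra_special)))
  tokens <- c(specials, sort(unique(setdiff(event_tokens, specials))))
  .new_vocab(tokens, lab_deciles = lab_deciles)
}

#' Build the token vocabulary from a cohort
#'
#' Applies, in order: code mapping, diagnosis grouping, the per-patient
#' rare-code frequency filter, and per-lab eCDF decile fitting on the
#' training split. Token ids are assigned deterministically: structural
#' tokens first (PAD, SEP, T0-T3), then sex and age buckets, then
#' visit-type/discharge tokens observed in the data, then the retained event
#' tokens in sorted order (each retained lab contributes its ten decile
#' tokens).
#'
#' @param records an `ehr_cohort` / list of `ehr_record`.
#' @param mapping optional `ehr_code_mapping`.
#' @param threshold rare-code removal fraction, default 0.001.
#' @param train_ids person ids forming the training split for decile fitting
#'   (default: all patients).
#' @return an `ehr_vocab`.
#' @export
build_vocabulary <- function(records, mapping = NULL, threshold = 0.001,
                             train_ids = NULL) {
  if (!length(records)) stop("records must be non-empty", call. = FALSE)
  freq <- compute_code_frequencies(records, mapping)
  kept <- filter_rare_codes(freq, length(records), threshold)
  if (!length(kept)) stop("vocabulary is empty after the rare-code filter", call. = FALSE)
  dom <- attr(kept, "domain")

  # training lab values for retained labs
  if (is.null(train_ids)) {
    train_ids <- vapply(records, function(r) as.numeric(r$person_id), numeric(1))
  }
  lab_codes <- names(kept)[dom == "lab"]
  lab_values <- stats::setNames(
    replicate(length(lab_codes), numeric(0), simplify = FALSE), lab_codes)
  for (r in records) {
    if (!r$person_id %in% train_ids) next
    for (v in r$visits) {
      ev <- v$events
      idx <- which(ev$domain == "lab")
      for (i in idx) {
        code <- .normalize_domain_codes(ev$code[i], "lab", mapping)
        if (code %in% lab_codes) {
          lab_values[[code]] <- c(lab_values[[code]], ev$value[i])
        }
      }
    }
  }
  deciles <- suppressWarnings(fit_lab_deciles(lab_values))
  dropped_labs <- setdiff(lab_codes, names(deciles))
  if (length(dropped_labs)) {
    warning(sprintf("excluded %d lab code(s) with insufficient training values: %s",
                    length(dropped_labs), paste(dropped_labs, collapse = ", ")),
            call. = FALSE)
  }

  event_tokens <- character(0)
  for (i in seq_along(kept)) {
    d <- dom[i]; code <- names(kept)[i]
    if (d == "lab") {
      if (code %in% names(deciles)) {
        event_tokens <- c(event_tokens, sprintf("LAB:%s:%d", code, 0:9))
      }
    } else {
      event_tokens <- c(event_tokens, paste0(.domain_prefix[[d]], code))
    }
  }

  vt <- sort(unique(unlist(lapply(records, function(r)
    vapply(r$visits, function(v) v$visit_type, character(1))))))
  dt <- sort(unique(stats::na.omit(unlist(lapply(records, function(r)
    vapply(r$visits, function(v) v$discharge, character(1)))))))
  extra <- c(paste0("VT:", vt), if (length(dt)) paste0("DT:", dt))

  specials <- c(.STRUCTURAL_TOKENS, .SEX_TOKENS, .AGE_TOKENS, extra)
  tokens <- c(specials, sort(unique(event_tokens)))
  .new_vocab(tokens, lab_deciles = deciles,
             frequencies = stats::setNames(as.integer(kept), names(kept)),
             threshold = threshold, n_patients = length(records))
}

#' @export
print.ehr_vocab <- function(x, ...) {
  n_lab <- length(x$lab_deciles)
  cat(sprintf("EHR token vocabulary: %d tokens (%d structural/special, %d lab codes with deciles)\n",
              length(x$tokens), sum(!grepl("^(DX|RX|PX|LAB):", x$tokens)), n_lab))
  if (!is.na(x$threshold)) {
    cat(sprintf("  rare-code threshold %.4g over %d patients\n", x$threshold, x$n_patients))
  }
  invisible(x)
}

#' Token ids for token strings (and back)
#'
#' @param vocab an `ehr_vocab`.
#' @param tokens character vector of tokens.
#' @return `encode_tokens`: integer ids (NA for unknown tokens);
#'   `decode_tokens`: token strings.
#' @export
encode_tokens <- function(vocab, tokens) {
  unname(vocab$token_to_id[tokens])
}

#' @rdname encode_tokens
#' @param ids integer token ids.
#' @export
decode_tokens <- function(vocab, ids) {
  vocab$tokens[ids]
}

#' Serialize a vocabulary to JSON (and back)
#'
#' @param vocab an `ehr_vocab`.
#' @param path file path for the JSON vocabulary.
#' @return `write_vocabulary`: invisibly, `path`; `read_vocabulary`: the
#'   `ehr_vocab`.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "ehr_vocab"))
  jsonlite::write_json(
    list(version = vocab$version,
         tokens = vocab$tokens,
         lab_deciles = vocab$lab_deciles,
         frequencies = as.list(vocab$frequencies),
         threshold = vocab$threshold,
         n_patients = vocab$n_patients),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  freq <- if (length(x$frequencies)) {
    stats::setNames(as.integer(unlist(x$frequencies)), names(x$frequencies))
  } else integer(0)
  .new_vocab(x$tokens,
             lab_deciles = lapply(x$lab_deciles, as.numeric),
             frequencies = freq,
             threshold = x$threshold %||% NA_real_,
             n_patients = as.integer(x$n_patients %||% NA_integer_))
}

# token classification helpers used across modules
.is_event_token <- function(tokens) grepl("^(DX|RX|PX|LAB):", tokens)
.is_time_token <- function(tokens) tokens %in% .TIME_TOKENS
.structural_ids <- function(vocab) {
  list(pad = vocab$token_to_id[["PAD"]],
       sep = vocab$token_to_id[["SEP"]],
       time = unname(vocab$token_to_id[.TIME_TOKENS]))
}
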