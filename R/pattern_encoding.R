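# Pattern-based encoding of predicted surface accessibility (SA: E exposed /
# B buried) and secondary structure (SS: H helix / E sheet / C coil).
# Each 25-mer window is split into an N-terminal region (ending at position
# 12), the sequon region (positions 13-15), and a C-terminal region (starting
# at position 16). Terminal-region pattern length w is selected per region by
# maximising the average pattern deviation APD_w; the sequon region is fixed
# at w = 3. Positions outside the protein carry the pad character '-'.

PAD_CHAR <- "-"
SEQUON_REGION_W <- 3L
PATTERN_W_RANGE <- 3:11

#' Extract a region pattern from a per-residue annotation string
#'
#' @param ann Annotation string of window length (default 25) over the SA or
#'   SS class alphabet plus the pad character `-`.
#' @param region One of `"N_terminal"`, `"sequon"`, `"C_terminal"`.
#' @param w Pattern length: 3..11 for terminal regions; the sequon region is
#'   fixed at 3.
#' @param l Window length (default 25).
#' @return The pattern substring: N-terminal patterns end at the residue
#'   adjacent to the sequon (position 12), C-terminal patterns start just
#'   after it (position 16).
#' @export
extract_region_pattern <- function(ann, region = c("N_terminal", "sequon", "C_terminal"),
                                   w = SEQUON_REGION_W, l = 25L) {
  region <- match.arg(region)
  stopifnot(nchar(ann) == l)
  centre <- (l + 1L) %/% 2L
  if (region == "sequon") {
    if (w != SEQUON_REGION_W) stop("sequon region pattern length is fixed at 3")
    return(substr(ann, centre, centre + 2L))
  }
  if (w < min(PATTERN_W_RANGE) || w > max(PATTERN_W_RANGE)) {
    stop("terminal-region pattern length w must be in [3, 11], got ", w)
  }
  if (region == "N_terminal") {
    substr(ann, centre - w, centre - 1L)
  } else {
    substr(ann, centre + 3L, centre + 2L + w)
  }
}

#' Build a pattern vocabulary for one (feature type, region, w) combination
#'
#' Counts each pattern's occurrences in glycosite (`e_i`) and non-glycosite
#' (`n_i`) windows. Patterns occurring in fewer than 1% of windows are
#' grouped into a single "other" bucket, as are patterns containing the pad
#' character and patterns never seen in negatives (whose class ratio would be
#' infinite).
#'
#' @param anns Character vector of window-length annotation strings.
#' @param labels Binary labels (logical, or `"positive"`/`"negative"`).
#' @param feature_type `"SA"` or `"SS"` (metadata only).
#' @param region `"N_terminal"`, `"sequon"` or `"C_terminal"`.
#' @param w Pattern length.
#' @param rare_threshold Rare-pattern frequency floor (default 0.01);
#'   patterns with total count below `ceiling(rare_threshold * n_windows)`
#'   are merged.
#' @return A `pattern_vocab` object: retained patterns with per-class counts,
#'   the other bucket, the background ratio `z` (positive / negative window
#'   count), and sizing metadata.
#' @export
build_vocabulary <- function(anns, labels, feature_type = c("SA", "SS"),
                             region = c("N_terminal", "sequon", "C_terminal"),
                             w = SEQUON_REGION_W, rare_threshold = 0.01) {
  feature_type <- match.arg(feature_type)
  region <- match.arg(region)
  lab <- .as_binary_label(labels)
  if (!any(lab) || all(lab)) stop("both classes required to build a vocabulary")
  pats <- vapply(anns, extract_region_pattern, character(1),
                 region = region, w = w)
  n_windows <- length(pats)
  e <- table(factor(pats[lab], levels = unique(pats)))
  n <- table(factor(pats[!lab], levels = unique(pats)))
  tot <- as.integer(e) + as.integer(n)
  df <- data.frame(pattern = names(e), e = as.integer(e), n = as.integer(n),
                   total = tot, stringsAsFactors = FALSE)
  floor_count <- ceiling(rare_threshold * n_windows)
  merge <- df$total < floor_count |
    grepl(PAD_CHAR, df$pattern, fixed = TRUE) |
    df$n == 0L
  other <- c(e = sum(df$e[merge]), n = sum(df$n[merge]))
  kept <- df[!merge, c("pattern", "e", "n")]
  kept <- kept[order(-(kept$e + kept$n), kept$pattern), , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(
    feature_type = feature_type, region = region, w = as.integer(w),
    patterns = kept, other = other,
    n_windows = n_windows, z = sum(lab) / sum(!lab),
    rare_threshold = rare_threshold),
    class = "pattern_vocab")
}

#' Average pattern deviation of a vocabulary
#'
#' The occurrence-weighted mean absolute deviation of each pattern's class
#' ratio `e_i / n_i` from the background ratio `z`:
#' `APD = sum(|e_i/n_i - z| * (e_i + n_i)) / sum(e_i + n_i)`,
#' summed over retained patterns and the other bucket. An other bucket with
#' `n = 0` (possible only when every merged occurrence is positive) has an
#' infinite ratio and is dropped from both sums.
#'
#' @param vocab A `pattern_vocab`.
#' @return Non-negative scalar.
#' @export
compute_apd <- function(vocab) {
  stopifnot(inherits(vocab, "pattern_vocab"))
  e <- vocab$patterns$e
  n <- vocab$patterns$n
  if (vocab$other[["e"]] + vocab$other[["n"]] > 0) {
    e <- c(e, vocab$other[["e"]])
    n <- c(n, vocab$other[["n"]])
  }
  ok <- n > 0
  e <- e[ok]; n <- n[ok]
  if (!length(e)) stop("vocabulary has no patterns with defined class ratio")
  sum(abs(e / n - vocab$z) * (e + n)) / sum(e + n)
}

#' Select the terminal-region pattern length maximising APD
#'
#' Builds vocabularies for every `w` in `w_range` and returns the one whose
#' APD is largest; ties break toward the smaller (simpler) length.
#'
#' @inheritParams build_vocabulary
#' @param w_range Candidate lengths (default 3..11).
#' @return List with `w_star`, the winning `vocab`, and the full `apd` sweep
#'   (named numeric vector).
#' @export
select_window_length <- function(anns, labels, feature_type = c("SA", "SS"),
                                 region = c("N_terminal", "C_terminal"),
                                 w_range = PATTERN_W_RANGE,
                                 rare_threshold = 0.01) {
  feature_type <- match.arg(feature_type)
  region <- match.arg(region)
  vocabs <- lapply(w_range, function(w) {
    build_vocabulary(anns, labels, feature_type, region, w, rare_threshold)
  })
  apd <- vapply(vocabs, compute_apd, numeric(1))
  names(apd) <- w_range
  best <- which.max(apd)  # first maximum, w_range ascending => smallest w
  list(w_star = as.integer(w_range[best]), vocab = vocabs[[best]], apd = apd)
}

#' Fit the six pattern vocabularies used by the classifier
#'
#' For each feature type (SA, SS) the terminal-region pattern lengths are
#' chosen by APD maximisation and the sequon region is fixed at length 3.
#'
#' @param sa Character vector of SA annotation strings (window length).
#' @param ss Character vector of SS annotation strings.
#' @param labels Binary labels.
#' @param rare_threshold Rare-pattern floor (default 0.01).
#' @return A `pattern_vocab_set`: named list of six `pattern_vocab` objects
#'   (`sa_n`, `sa_seq`, `sa_c`, `ss_n`, `ss_seq`, `ss_c`).
#' @export
fit_pattern_vocabularies <- function(sa, ss, labels, rare_threshold = 0.01) {
  fit_one <- function(anns, ft) {
    list(
      n = select_window_length(anns, labels, ft, "N_terminal",
                               rare_threshold = rare_threshold)$vocab,
      seq = build_vocabulary(anns, labels, ft, "sequon", SEQUON_REGION_W,
                             rare_threshold),
      c = select_window_length(anns, labels, ft, "C_terminal",
                               rare_threshold = rare_threshold)$vocab)
  }
  sa_v <- fit_one(sa, "SA")
  ss_v <- fit_one(ss, "SS")
  structure(list(sa_n = sa_v$n, sa_seq = sa_v$seq, sa_c = sa_v$c,
                 ss_n = ss_v$n, ss_seq = ss_v$seq, ss_c = ss_v$c),
            class = "pattern_vocab_set")
}

.vocab_block_size <- function(vocab) {
  nrow(vocab$patterns) + as.integer(sum(vocab$other) > 0)
}

.encode_block <- function(anns, vocab) {
  pats <- vapply(anns, extract_region_pattern, character(1),
                 region = vocab$region, w = vocab$w)
  size <- .vocab_block_size(vocab)
  has_other <- sum(vocab$other) > 0
  idx <- match(pats, vocab$patterns$pattern)
  if (has_other) idx[is.na(idx)] <- size
  m <- matrix(0L, nrow = length(pats), ncol = size)
  hit <- !is.na(idx)
  m[cbind(which(hit), idx[hit])] <- 1L
  colnames(m) <- c(
    paste(tolower(vocab$feature_type), substr(vocab$region, 1, 1),
          vocab$patterns$pattern, sep = "_"),
    if (has_other) paste(tolower(vocab$feature_type),
                         substr(vocab$region, 1, 1), "other", sep = "_"))
  m
}

#' One-hot encode windows against fitted pattern vocabularies
#'
#' Region blocks are concatenated in order N-terminal, sequon, C-terminal
#' within each feature type (SA first, then SS). Within each block exactly
#' one position is 1: the matched pattern, or the other bucket when the
#' pattern was rare or unseen at training time.
#'
#' @param sa,ss Character vectors of annotation strings.
#' @param vocabs A `pattern_vocab_set` from [fit_pattern_vocabularies()].
#' @return Binary integer matrix, one row per window.
#' @export
encode_patterns <- function(sa, ss, vocabs) {
  stopifnot(inherits(vocabs, "pattern_vocab_set"))
  l <- unique(c(nchar(sa), nchar(ss)))
  if (length(l) != 1L) stop("all annotation strings must share the window length")
  blocks <- list(.encode_block(sa, vocabs$sa_n), .encode_block(sa, vocabs$sa_seq),
                 .encode_block(sa, vocabs$sa_c), .encode_block(ss, vocabs$ss_n),
                 .encode_block(ss, vocabs$ss_seq), .encode_block(ss, vocabs$ss_c))
  do.call(cbind, blocks)
}

#' Slice a per-protein annotation string to a sequon window
#'
#' @param ann Full-protein annotation string (one class character per
#'   residue).
#' @param position 1-based sequon asparagine position.
#' @param l Window length (default 25).
#' @return Window-length string padded with `-` outside the protein.
#' @export
extract_annotation_window <- function(ann, position, l = 25L) {
  n <- nchar(ann)
  half <- (l - 1L) %/% 2L
  from <- position - half
  to <- position + half
  core <- substr(ann, max(1L, from), min(n, to))
  paste0(strrep(PAD_CHAR, max(0L, 1L - from)), core,
         strrep(PAD_CHAR, max(0L, to - n)))
}

#' Read per-residue SA/SS class predictions from a tabular file
#'
#' Adapter for external surface-accessibility / secondary-structure
#' predictors. Accepts a whitespace- or tab-delimited table whose header
#' names include `position` plus `sa` and/or `ss` (a `residue` column, when
#' present, is checked downstream). Any tool emitting per-residue {E,B} and
#' {H,E,C} classes can back this contract.
#'
#' @param path Path to the table.
#' @return data.frame with `position` and the available class columns, plus
#'   `sa`/`ss` strings assembled in position order as attributes `sa_string`
#'   and `ss_string`.
#' @export
read_residue_classes <- function(path) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!"position" %in% names(df)) stop("residue class table needs a 'position' column")
  if (!any(c("sa", "ss") %in% names(df))) {
    stop("residue class table needs an 'sa' and/or 'ss' column")
  }
  df <- df[order(df$position), , drop = FALSE]
  if (!identical(as.integer(df$position), seq_len(nrow(df)))) {
    stop("residue class table positions must be 1..n without gaps")
  }
  if ("sa" %in% names(df)) attr(df, "sa_string") <- paste(df$sa, collapse = "")
  if ("ss" %in% names(df)) attr(df, "ss_string") <- paste(df$ss, collapse = "")
  df
}
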