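# Gapped-dipeptide (GD) features. A gapped dipeptide pairs the sequon
# asparagine with a flanking residue A at gap k: "A{k}N" when A lies k
# residues upstream (N-terminal side), "N{k}A" when k residues downstream.
# For a 25-mer window k runs 0..11 on each side; the C-terminal gap-1
# position is the sequon S/T itself, so N1S/N1T carry no signal and are
# excluded, leaving 23 dipeptides per window.

GD_MAX_GAP <- 11L

# canonical (side, gap) layout: N-terminal gaps 11..0, then C-terminal 0,2..11
.gd_layout <- function() {
  data.frame(
    side = c(rep("N_terminal", GD_MAX_GAP + 1L), rep("C_terminal", GD_MAX_GAP)),
    gap = c(GD_MAX_GAP:0L, 0L, 2:GD_MAX_GAP),
    stringsAsFactors = FALSE)
}

.gd_name <- function(residue, gap, side) {
  n <- max(length(residue), length(gap), length(side))
  residue <- rep_len(residue, n)
  gap <- rep_len(gap, n)
  side <- rep_len(side, n)
  ifelse(side == "N_terminal", paste0(residue, gap, "N"), paste0("N", gap, residue))
}

#' Enumerate the 23 gapped dipeptides of a sequon window
#'
#' @param window A 25-mer sequon window string with the asparagine at the
#'   centre (position 13).
#' @return Character vector of 23 canonical dipeptide names, ordered
#'   N-terminal gaps 11..0 then C-terminal gaps 0, 2..11.
#' @examples
#' w <- paste0(strrep("A", 11), "W", "NGT", strrep("A", 10))
#' enumerate_window_gds(w)
#' @export
enumerate_window_gds <- function(window) {
  l <- 2L * (GD_MAX_GAP + 1L) + 1L  # 25
  if (nchar(window) != l) stop("window must have length ", l, ", got ", nchar(window))
  centre <- (l + 1L) %/% 2L
  if (substr(window, centre, centre) != "N") stop("window centre must be 'N'")
  chars <- strsplit(window, "")[[1]]
  lay <- .gd_layout()
  pos <- ifelse(lay$side == "N_terminal", centre - lay$gap - 1L, centre + lay$gap + 1L)
  .gd_name(chars[pos], lay$gap, lay$side)
}

# unambiguous internal key: the display name "N5N" is shared by the
# N-terminal and C-terminal residue-N dipeptides at gap 5, so counting and
# lookup key on (side, gap, residue)
.gd_key <- function(residue, gap, side) paste(side, gap, residue, sep = ":")

.window_gd_keys <- function(window) {
  l <- 2L * (GD_MAX_GAP + 1L) + 1L
  centre <- (l + 1L) %/% 2L
  chars <- strsplit(window, "")[[1]]
  lay <- .gd_layout()
  pos <- ifelse(lay$side == "N_terminal", centre - lay$gap - 1L, centre + lay$gap + 1L)
  .gd_key(chars[pos], lay$gap, lay$side)
}

#' Enumerate the full gapped-dipeptide feature space
#'
#' All realizable dipeptide types over the 20 standard amino acids for
#' sequon-centred 25-mers: 12 N-terminal gaps x 20 residues plus 11
#' C-terminal gaps x 20 residues (gap 1 on the C-terminal side is always the
#' sequon S/T and is excluded), i.e. 460 types. A type is the triple
#' (side, gap, residue); display names collide for residue N, where "NkN"
#' reads the same from either side.
#'
#' @return data.frame with one row per type: `gd` (display name), `side`,
#'   `gap`, `residue`.
#' @export
gd_feature_space <- function() {
  lay <- .gd_layout()
  data.frame(
    gd = unlist(lapply(seq_len(nrow(lay)), function(i) {
      .gd_name(AA_STANDARD, lay$gap[i], lay$side[i])
    })),
    side = rep(lay$side, each = length(AA_STANDARD)),
    gap = rep(lay$gap, each = length(AA_STANDARD)),
    residue = rep(AA_STANDARD, times = nrow(lay)),
    stringsAsFactors = FALSE)
}

#' Fit the gapped-dipeptide ratio (GDR) table
#'
#' Counts each dipeptide's occurrences among positive (glycosite) and
#' negative (non-glycosite) windows and forms the odds-ratio-style GDR: the
#' dipeptide's share of all positive-class occurrences divided by its share
#' of all negative-class occurrences. Dipeptides involving padding or
#' ambiguity letters carry no learned statistic and are never counted;
#' dipeptides absent from the negative class have an undefined (NA) GDR
#' unless a pseudocount is supplied.
#'
#' @param windows Character vector of 25-mer sequon windows.
#' @param labels Vector coercible to `"positive"`/`"negative"` (or logical,
#'   `TRUE` = positive). Both classes must be present.
#' @param pseudocount Additive smoothing constant (default 0, so ratios are
#'   reproducible directly from raw counts).
#' @return A `gdr_table` data.frame with one row per feature-space dipeptide:
#'   `gd`, `side`, `gap`, `residue`, `pos_count`, `neg_count`, `gdr`,
#'   `normalized_gdr` (filled by [normalize_gdr()]).
#' @export
fit_gdr <- function(windows, labels, pseudocount = 0) {
  lab <- .as_binary_label(labels)
  if (!any(lab) || all(lab)) {
    stop("fit_gdr requires both positive and negative windows")
  }
  space <- gd_feature_space()
  keys <- .gd_key(space$residue, space$gap, space$side)
  gds <- lapply(windows, .window_gd_keys)
  count_class <- function(idx) {
    tab <- table(factor(unlist(gds[idx]), levels = keys))
    as.integer(tab)
  }
  pos_count <- count_class(which(lab))
  neg_count <- count_class(which(!lab))
  pc <- pos_count + pseudocount
  nc <- neg_count + pseudocount
  pos_share <- pc / sum(pc)
  neg_share <- nc / sum(nc)
  gdr <- ifelse(nc > 0, pos_share / neg_share, NA_real_)
  tbl <- data.frame(
    gd = space$gd, side = space$side, gap = space$gap, residue = space$residue,
    pos_count = pos_count, neg_count = neg_count,
    gdr = gdr, normalized_gdr = NA_real_,
    stringsAsFactors = FALSE)
  attr(tbl, "n_pos_windows") <- sum(lab)
  attr(tbl, "n_neg_windows") <- sum(!lab)
  attr(tbl, "pseudocount") <- pseudocount
  attr(tbl, "normalized") <- FALSE
  class(tbl) <- c("gdr_table", "data.frame")
  tbl
}

.as_binary_label <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- as.character(labels)
  if (!all(l %in% c("positive", "negative"))) {
    stop("labels must be logical or 'positive'/'negative'")
  }
  l == "positive"
}

#' Min-max normalise a GDR table within each (gap, side) class
#'
#' Within every (gap, side) class the minimum defined GDR maps to 0 and the
#' maximum to 1. A degenerate class (all defined GDRs equal) maps to the
#' neutral midpoint 0.5. Undefined GDRs stay NA and are excluded from the
#' min/max ranking.
#'
#' @param table A `gdr_table` from [fit_gdr()].
#' @return The table with `normalized_gdr` filled in.
#' @export
normalize_gdr <- function(table) {
  stopifnot(inherits(table, "gdr_table"))
  key <- paste(table$side, table$gap)
  norm <- rep(NA_real_, nrow(table))
  for (k in unique(key)) {
    i <- which(key == k & !is.na(table$gdr))
    if (!length(i)) next
    v <- table$gdr[i]
    rng <- range(v)
    norm[i] <- if (rng[1] == rng[2]) 0.5 else (v - rng[1]) / (rng[2] - rng[1])
  }
  table$normalized_gdr <- norm
  attr(table, "normalized") <- TRUE
  table
}

#' Encode sequon windows as 23-dimensional normalised-GDR vectors
#'
#' Each window's 23 dipeptides are looked up in the fitted table in canonical
#' order. Dipeptides that are undefined, unseen at training time, or involve
#' padding/ambiguity letters encode as the neutral midpoint 0.5, so padding
#' never pushes a prediction either way.
#'
#' @param windows Character vector of 25-mer windows.
#' @param table A normalised `gdr_table`.
#' @return Numeric matrix, one row per window, 23 columns named by canonical
#'   (side, gap) slot.
#' @export
encode_gd <- function(windows, table) {
  stopifnot(inherits(table, "gdr_table"))
  if (!isTRUE(attr(table, "normalized"))) {
    stop("GDR table must be normalised before encoding (see normalize_gdr)")
  }
  lut <- setNames(table$normalized_gdr,
                  .gd_key(table$residue, table$gap, table$side))
  lay <- .gd_layout()
  slot_names <- ifelse(lay$side == "N_terminal",
                       paste0("gd_A", lay$gap, "N"), paste0("gd_N", lay$gap, "A"))
  m <- t(vapply(windows, function(w) {
    v <- lut[.window_gd_keys(w)]
    v[is.na(v)] <- 0.5
    unname(v)
  }, numeric(nrow(lay))))
  colnames(m) <- slot_names
  rownames(m) <- NULL
  m
}

#' Write / read a GDR table as TSV
#'
#' @param table A `gdr_table`.
#' @param path Output path.
#' @return `write_gdr_table` returns `path` invisibly; `read_gdr_table`
#'   returns the reconstructed `gdr_table`.
#' @export
write_gdr_table <- function(table, path) {
  df <- as.data.frame(table)
  df$n_pos_windows <- attr(table, "n_pos_windows")
  df$n_neg_windows <- attr(table, "n_neg_windows")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gdr_table
#' @export
read_gdr_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  tbl <- df[setdiff(names(df), c("n_pos_windows", "n_neg_windows"))]
  attr(tbl, "n_pos_windows") <- df$n_pos_windows[1]
  attr(tbl, "n_neg_windows") <- df$n_neg_windows[1]
  attr(tbl, "normalized") <- !all(is.na(tbl$normalized_gdr))
  class(tbl) <- c("gdr_table", "data.frame")
  tbl
}
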