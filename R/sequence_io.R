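# Sequence and annotation input: FASTA parsing, sequon location, window
# extraction, and labelled dataset assembly.

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "O", "J")

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and stop characters (`*`) stripped. The first
#' whitespace-delimited token of each header is taken as the protein id,
#' matching UniProt-style FASTA exports.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param label Optional label applied to every record: one of
#'   `"glycoprotein"`, `"non_glycoprotein"`, `"unknown"`.
#' @return A data.frame with columns `id`, `sequence`, `label`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 test", "MKNGSA"), fa)
#' parse_fasta(fa)
#' @export
parse_fasta <- function(path, label = c("unknown", "glycoprotein", "non_glycoprotein")) {
  label <- match.arg(label)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(aas))
  seqs <- toupper(gsub("\\*", "", as.character(aas)))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for FASTA entry: ", paste(ids[empty], collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate protein ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs), label = label,
             stringsAsFactors = FALSE)
}

#' Locate N-X-S/T sequons in a protein sequence
#'
#' Returns 1-based positions of asparagines in N-X-S/T sequons. N-X-C motifs
#' are never reported. By default sequons with proline at the X position are
#' excluded (proline blocks glycosylation), as are sequons whose X position is
#' an ambiguity letter of unknown identity.
#'
#' @param sequence Protein sequence string.
#' @param exclude_center_proline Drop N-P-S/T sequons (default `TRUE`).
#' @param include_x_middle Keep sequons whose middle residue is an ambiguity
#'   letter (X/B/Z/U/O/J); default `FALSE`.
#' @return Integer vector of asparagine positions (possibly empty).
#' @examples
#' find_sequons("MNGSA")  # 2
#' find_sequons("MNPSA")  # excluded
#' @export
find_sequons <- function(sequence, exclude_center_proline = TRUE,
                         include_x_middle = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  if (n < 3L) return(integer())
  p <- which(chars[seq_len(n - 2L)] == "N" &
             chars[3:n] %in% c("S", "T"))
  mid <- chars[p + 1L]
  keep <- rep(TRUE, length(p))
  if (exclude_center_proline) keep <- keep & mid != "P"
  if (!include_x_middle) keep <- keep & !(mid %in% AA_AMBIGUOUS)
  p[keep]
}

#' Extract an l-mer window centred on a sequon asparagine
#'
#' Positions outside the protein are padded with the dummy residue `'X'`, so
#' windows near either terminus keep the asparagine at the exact centre.
#'
#' @param sequence Protein sequence string.
#' @param position 1-based asparagine position of a sequon.
#' @param l Odd window length, `l >= 5` (default 25).
#' @return The window string of length `l`.
#' @export
extract_window <- function(sequence, position, l = 25L) {
  if (l %% 2L != 1L || l < 5L) stop("window length l must be odd and >= 5, got ", l)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  stopifnot(position >= 1L, position <= n)
  if (substr(sequence, position, position) != "N") {
    stop("position ", position, " is not an asparagine")
  }
  half <- (l - 1L) %/% 2L
  from <- position - half
  to <- position + half
  left_pad <- max(0L, 1L - from)
  right_pad <- max(0L, to - n)
  core <- substr(sequence, max(1L, from), min(n, to))
  paste0(strrep("X", left_pad), core, strrep("X", right_pad))
}

.normalize_status <- function(status) {
  s <- tolower(trimws(status))
  excluded <- c("excluded_evidence", "probable", "potential",
                "by sequence similarity", "by_sequence_similarity")
  out <- rep(NA_character_, length(s))
  out[s %in% c("validated_glycosite", "glycosite", "validated")] <- "validated_glycosite"
  out[s %in% c("non_glycosite", "negative", "non-glycosite")] <- "non_glycosite"
  out[s %in% excluded] <- "excluded_evidence"
  if (anyNA(out)) {
    stop("unrecognised annotation status: ",
         paste(unique(status[is.na(out)]), collapse = ", "))
  }
  out
}

#' Load a site-annotation table and validate it against sequences
#'
#' Reads a delimited text table (TSV or CSV, auto-detected from the header
#' line) with columns `protein_id`, `position`, `status`. Statuses
#' `"Probable"`, `"Potential"` and `"By sequence similarity"` map to
#' `excluded_evidence`; such rows are retained but flagged and never enter
#' training or evaluation. Every annotated position must be an asparagine in
#' the corresponding sequence.
#'
#' @param path Path to the annotation table, or a data.frame with the same
#'   columns.
#' @param proteins data.frame from [parse_fasta()] (columns `id`, `sequence`).
#' @return data.frame with columns `protein_id`, `position`, `status`.
#' @export
load_annotations <- function(path, proteins) {
  if (is.data.frame(path)) {
    ann <- path
  } else {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    ann <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  }
  req <- c("protein_id", "position", "status")
  if (!all(req %in% names(ann))) {
    stop("annotation table must have columns: ", paste(req, collapse = ", "))
  }
  ann <- ann[req]
  ann$position <- as.integer(ann$position)
  ann$status <- .normalize_status(ann$status)
  unknown <- setdiff(ann$protein_id, proteins$id)
  if (length(unknown)) {
    stop("annotations reference unknown proteins: ",
         paste(unique(unknown), collapse = ", "))
  }
  seqs <- setNames(proteins$sequence, proteins$id)
  res <- substr(seqs[ann$protein_id], ann$position, ann$position)
  bad <- which(res != "N")
  if (length(bad)) {
    stop("annotated position is not an asparagine: ",
         paste(sprintf("%s:%d(%s)", ann$protein_id[bad], ann$position[bad],
                       res[bad]), collapse = ", "))
  }
  ann
}

#' Assemble a labelled sequon-window dataset
#'
#' Positives are experimentally validated glycosites. Negatives are the
#' unannotated sequons of glycoproteins plus every sequon of
#' non-glycoproteins. Sequons with excluded-evidence annotations are omitted
#' entirely, since their glycosylation status is uncertain.
#'
#' @param proteins data.frame with columns `id`, `sequence`, `label`
#'   (`"glycoprotein"` / `"non_glycoprotein"` / `"unknown"`).
#' @param annotations data.frame from [load_annotations()]; may be `NULL` for
#'   unlabelled prediction input.
#' @param l Window length (odd, default 25).
#' @param include_x_middle Passed to [find_sequons()].
#' @return data.frame of sequon windows with columns `protein_id`, `position`,
#'   `window`, `label` (`"positive"` / `"negative"` / `"unlabeled"`).
#' @export
build_dataset <- function(proteins, annotations = NULL, l = 25L,
                          include_x_middle = FALSE) {
  rows <- vector("list", nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    pid <- proteins$id[i]
    seqn <- proteins$sequence[i]
    plab <- proteins$label[i]
    pos <- find_sequons(seqn, include_x_middle = include_x_middle)
    if (!length(pos)) next
    status <- rep(NA_character_, length(pos))
    if (!is.null(annotations)) {
      a <- annotations[annotations$protein_id == pid, , drop = FALSE]
      m <- match(pos, a$position)
      status <- a$status[m]
    }
    label <- rep("unlabeled", length(pos))
    label[!is.na(status) & status == "validated_glycosite"] <- "positive"
    label[!is.na(status) & status == "non_glycosite"] <- "negative"
    if (plab == "glycoprotein") {
      label[is.na(status)] <- "negative"
    } else if (plab == "non_glycoprotein") {
      label[is.na(status)] <- "negative"
    }
    drop <- !is.na(status) & status == "excluded_evidence"
    pos <- pos[!drop]; label <- label[!drop]
    if (!length(pos)) next
    rows[[i]] <- data.frame(
      protein_id = pid, position = pos,
      window = vapply(pos, function(p) extract_window(seqn, p, l), character(1)),
      label = label, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), position = integer(),
                      window = character(), label = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
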