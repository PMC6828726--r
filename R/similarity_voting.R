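# Stage 1: protein-level similarity voting. Each protein P has a
# similar-protein set S(P): homology-search hits retained at probability
# >= 0.5. Training proteins whose sets share at least k_min members with the
# query's set act as templates and vote with weight overlap^2 for their own
# label (glycoprotein / non-glycoprotein).

#' Parse a homology-search hit list into a similar-protein set
#'
#' Accepts either a simplified two-column TSV (`hit_id`, `probability`,
#' header optional) or the summary block of a profile-HMM search tool
#' (columns: rank, hit id, probability, ...). Probabilities given as percents
#' (> 1) are divided by 100. Hits below the probability threshold and
#' self-hits are removed.
#'
#' @param path Path to the hit-list file.
#' @param query_id Id of the query protein (used to drop self-hits and to
#'   label the set).
#' @param prob_threshold Retention threshold on the hit probability
#'   (default 0.5).
#' @return A `homolog_set`: list with `protein_id`, `members` (character),
#'   and `prob` (named numeric, one value per member).
#' @export
parse_hit_list <- function(path, query_id, prob_threshold = 0.5) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ids <- character(); probs <- numeric()
  in_block <- FALSE
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (grepl("^\\s*No\\s+Hit", ln)) { in_block <- TRUE; next }
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (in_block || grepl("^\\s*[0-9]+\\s+\\S", ln) && length(f) >= 3 &&
        !is.na(suppressWarnings(as.numeric(f[1])))) {
      # summary-block style: rank, id, [description...], probability, ...
      if (is.na(suppressWarnings(as.integer(f[1])))) {
        stop("unparseable hit-list line ", k, " in ", path, ": ", ln)
      }
      num <- suppressWarnings(as.numeric(f[-(1:2)]))
      p <- num[which(!is.na(num))[1]]
      if (is.na(p)) stop("no probability found on hit-list line ", k, " in ", path)
      ids <- c(ids, f[2]); probs <- c(probs, p)
    } else if (length(f) == 2 && !is.na(suppressWarnings(as.numeric(f[2])))) {
      ids <- c(ids, f[1]); probs <- c(probs, as.numeric(f[2]))
    } else if (grepl("^(hit_id|#)", f[1], ignore.case = TRUE)) {
      next
    } else {
      stop("unparseable hit-list line ", k, " in ", path, ": ", ln)
    }
  }
  probs[probs > 1] <- probs[probs > 1] / 100
  keep <- probs >= prob_threshold & ids != query_id
  ids <- ids[keep]; probs <- probs[keep]
  dup <- duplicated(ids)
  homolog_set(query_id, ids[!dup], probs[!dup])
}

#' Construct a similar-protein set directly
#'
#' @param protein_id Query protein id.
#' @param members Character vector of hit ids (self-hits dropped).
#' @param prob Numeric vector of hit probabilities in `[0, 1]`; members below
#'   `prob_threshold` are dropped.
#' @param prob_threshold Retention threshold (default 0.5).
#' @return A `homolog_set`.
#' @export
homolog_set <- function(protein_id, members, prob = rep(1, length(members)),
                        prob_threshold = 0.5) {
  stopifnot(length(members) == length(prob))
  keep <- prob >= prob_threshold & members != protein_id
  members <- members[keep]; prob <- prob[keep]
  structure(list(protein_id = protein_id, members = members,
                 prob = setNames(prob, members)),
            class = "homolog_set")
}

#' Build a template index from labelled training homolog sets
#'
#' @param sets List of `homolog_set` objects for the training proteins.
#' @param labels Character vector (parallel to `sets`) of
#'   `"glycoprotein"` / `"non_glycoprotein"`.
#' @return A `template_index`: named list keyed by protein id with `members`
#'   and `label`.
#' @export
build_template_index <- function(sets, labels) {
  stopifnot(length(sets) == length(labels),
            all(labels %in% c("glycoprotein", "non_glycoprotein")))
  ids <- vapply(sets, `[[`, character(1), "protein_id")
  if (anyDuplicated(ids)) stop("duplicate protein ids in template index")
  idx <- lapply(seq_along(sets), function(i) {
    list(members = sets[[i]]$members, label = labels[i])
  })
  names(idx) <- ids
  structure(idx, class = "template_index")
}

#' Find template proteins for a query by similar-set overlap
#'
#' A training protein is a template when its similar-protein set shares at
#' least `k_min` members with the query's. The query's own index entry, if
#' present, is excluded (leave-self-out), so scoring a training protein never
#' consults itself.
#'
#' @param query A `homolog_set`.
#' @param index A `template_index`.
#' @param k_min Minimum shared-member count (default 5).
#' @return data.frame with columns `template_id`, `overlap`, `label`
#'   (zero rows when no template qualifies).
#' @export
find_templates <- function(query, index, k_min = 5L) {
  stopifnot(inherits(query, "homolog_set"), inherits(index, "template_index"))
  ids <- setdiff(names(index), query$protein_id)
  if (!length(query$members) || !length(ids)) {
    return(data.frame(template_id = character(), overlap = integer(),
                      label = character(), stringsAsFactors = FALSE))
  }
  overlap <- vapply(ids, function(id) {
    length(intersect(query$members, index[[id]]$members))
  }, integer(1))
  keep <- overlap >= k_min
  data.frame(template_id = ids[keep], overlap = unname(overlap[keep]),
             label = vapply(ids[keep], function(id) index[[id]]$label, character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Squared-overlap voting score for a query protein
#'
#' Glycoprotein templates contribute `overlap^2` to `v_g`, non-glycoprotein
#' templates to `v_ng`; the protein score is `v_g / (v_g + v_ng)`. With no
#' templates the score is undefined (`NA`) and downstream integration leaves
#' second-stage scores unadjusted.
#'
#' @param query A `homolog_set`.
#' @param templates data.frame from [find_templates()].
#' @return A `voting_result`: list with `protein_id`, `v_g`, `v_ng`, `score`,
#'   `templates`.
#' @export
voting_score <- function(query, templates) {
  sq <- templates$overlap^2
  v_g <- sum(sq[templates$label == "glycoprotein"])
  v_ng <- sum(sq[templates$label == "non_glycoprotein"])
  score <- if (v_g + v_ng > 0) v_g / (v_g + v_ng) else NA_real_
  structure(list(protein_id = query$protein_id, v_g = v_g, v_ng = v_ng,
                 score = score, templates = templates),
            class = "voting_result")
}

#' Score a set of proteins against a template index
#'
#' Convenience wrapper: [find_templates()] then [voting_score()] per query,
#' with leave-self-out handled by the index lookup.
#'
#' @param sets List of `homolog_set` queries.
#' @param index A `template_index`.
#' @param k_min Minimum overlap (default 5).
#' @return Named numeric vector of protein scores (`NA` where undefined).
#' @export
score_proteins <- function(sets, index, k_min = 5L) {
  out <- vapply(sets, function(s) {
    voting_score(s, find_templates(s, index, k_min))$score
  }, numeric(1))
  names(out) <- vapply(sets, `[[`, character(1), "protein_id")
  out
}

#' Summarise protein scores over five fixed intervals
#'
#' Groups defined scores into [0,0.2), [0.2,0.4), [0.4,0.6), [0.6,0.8),
#' [0.8,1.0] and reports per interval the protein count and the fraction of
#' glycoproteins `p_i`. With informative homology structure `p_i` increases
#' with score, motivating the 0.4 / 0.8 adjustment thresholds used at
#' integration.
#'
#' @param scores Numeric protein scores (NA allowed; dropped).
#' @param labels Parallel vector, `"glycoprotein"` / `"non_glycoprotein"`.
#' @return data.frame with `interval`, `n`, `n_glyco`, `p_glyco`.
#' @export
score_interval_summary <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  breaks <- c(0, 0.2, 0.4, 0.6, 0.8, 1.0)
  # right = FALSE + include.lowest closes only the top interval at 1.0
  bin <- cut(scores, breaks, right = FALSE, include.lowest = TRUE)
  n <- as.integer(table(bin))
  n_glyco <- as.integer(table(bin[labels == "glycoprotein"]))
  data.frame(interval = levels(bin), n = n, n_glyco = n_glyco,
             p_glyco = ifelse(n > 0, n_glyco / n, NA_real_),
             stringsAsFactors = FALSE)
}

#' Write / read a template index as TSV
#'
#' One row per training protein: `protein_id`, `label`, comma-joined member
#' ids.
#'
#' @param index A `template_index`.
#' @param path Output path.
#' @export
write_template_index <- function(index, path) {
  df <- data.frame(
    protein_id = names(index),
    label = vapply(index, `[[`, character(1), "label"),
    members = vapply(index, function(x) paste(x$members, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_template_index
#' @export
read_template_index <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  idx <- lapply(seq_len(nrow(df)), function(i) {
    m <- strsplit(df$members[i], ",", fixed = TRUE)[[1]]
    list(members = m[nzchar(m)], label = df$label[i])
  })
  names(idx) <- df$protein_id
  structure(idx, class = "template_index")
}
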