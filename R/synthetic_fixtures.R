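# Deterministic synthetic-data generators for every input the pipeline
# consumes: protein sequences with planted sequons and dipeptide enrichment,
# per-residue SA/SS annotation with a class-conditional sequon-proximal
# effect, and homolog-set universes with controllable within-class overlap.
# Each generator op draws from its own stream (master seed + fixed offset),
# so adding one op never shifts another op's draws.

.SEED_OFFSET <- c(proteins = 101L, annotations = 202L, homologs = 303L)

#' Configuration for the synthetic-data generators
#'
#' Defaults describe a moderately sized study with clearly plantable signal:
#' positive sequon windows are enriched (or depleted) for a set of
#' informative gapped dipeptides, their SA/SS annotations differ from
#' negatives at the sequon-proximal positions, and same-label proteins share
#' more homology-search hits than cross-label pairs.
#'
#' @param seed Master integer seed.
#' @param n_glycoproteins,n_non_glycoproteins Protein counts (40 / 40).
#' @param protein_length Length range, inclusive (150..400).
#' @param sequons_per_protein Planted sequons per protein (4).
#' @param pos_fraction Fraction of a glycoprotein's planted sequons that are
#'   glycosites (0.66, mirroring the roughly 2:1 ratio seen in curated
#'   sequon data).
#' @param excluded_fraction Fraction of glycosites annotated with
#'   excluded-evidence status instead (default 0).
#' @param planted_dipeptides data.frame with columns `residue`, `gap`,
#'   `side`, `factor`: the positive-class occurrence rate of the dipeptide
#'   is `factor` times the 1/20 background rate (capped at 0.95).
#' @param sa_effect,ss_effect Class-conditional shift of SA/SS emission
#'   probabilities at `effect_positions` (0.3).
#' @param effect_positions Window positions carrying the SA/SS effect
#'   (default 9..19: four residues either side of the sequon plus the sequon
#'   itself).
#' @param universe_size,mean_set_size Homolog universe: number of universe
#'   proteins (200) and members per similar-protein set (40).
#' @param overlap_boost In `[0, 1]`: fraction by which a protein's set
#'   favours its own label's half of the universe (0.6; 0 = no class
#'   structure).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_glycoproteins = 40L,
                             n_non_glycoproteins = 40L,
                             protein_length = c(150L, 400L),
                             sequons_per_protein = 4L,
                             pos_fraction = 0.66,
                             excluded_fraction = 0,
                             planted_dipeptides = default_planted_dipeptides(),
                             sa_effect = 0.3,
                             ss_effect = 0.3,
                             effect_positions = 9:19,
                             universe_size = 200L,
                             mean_set_size = 40L,
                             overlap_boost = 0.6) {
  stopifnot(n_glycoproteins > 0, n_non_glycoproteins > 0,
            sequons_per_protein > 0, pos_fraction > 0, pos_fraction <= 1,
            all(planted_dipeptides$factor > 0),
            sa_effect >= 0, sa_effect <= 0.5, ss_effect >= 0, ss_effect <= 1 / 3,
            overlap_boost >= 0, overlap_boost <= 1)
  structure(as.list(environment()), class = "generator_config")
}

#' Default planted-dipeptide table
#'
#' Six positive-oriented dipeptides enriched threefold and four
#' negative-oriented dipeptides depleted threefold in glycosite windows,
#' echoing the aromatic-residue enrichment and proline/lysine depletion seen
#' around real glycosites.
#'
#' @return data.frame with columns `residue`, `gap`, `side`, `factor`.
#' @export
default_planted_dipeptides <- function() {
  # one dipeptide per (side, gap) slot so plantings never overwrite each other
  data.frame(
    residue = c("W", "Y", "L", "Y", "H", "W", "P", "C", "K", "K"),
    gap =     c(5L, 0L, 10L, 7L, 6L, 11L, 2L, 4L, 9L, 4L),
    side = c(rep("N_terminal", 6L),
             "C_terminal", "N_terminal", "N_terminal", "C_terminal"),
    factor = c(rep(3, 6L), rep(1 / 3, 4L)),
    stringsAsFactors = FALSE)
}

.sample_aa <- function(n) sample(AA_STANDARD, n, replace = TRUE)

#' Generate synthetic proteins with planted sequons and annotations
#'
#' Sequences are drawn uniformly over the 20 standard residues; sequons are
#' planted at well-separated interior positions, labelled glycosite with
#' probability `pos_fraction` in glycoproteins, and the flanking residues of
#' each sequon are resampled so that each planted dipeptide occurs at
#' `factor` times the background rate in glycosite windows.
#'
#' @param config A `generator_config`.
#' @return List with `proteins` (data.frame `id`, `sequence`, `label`) and
#'   `annotations` (data.frame `protein_id`, `position`, `status`).
#' @export
generate_proteins <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + .SEED_OFFSET[["proteins"]])
  pd <- config$planted_dipeptides
  n_tot <- config$n_glycoproteins + config$n_non_glycoproteins
  labels <- rep(c("glycoprotein", "non_glycoprotein"),
                c(config$n_glycoproteins, config$n_non_glycoproteins))
  ids <- sprintf("SYN%04d", seq_len(n_tot))
  seqs <- character(n_tot)
  ann <- list()
  for (i in seq_len(n_tot)) {
    L <- sample(config$protein_length[1]:config$protein_length[2], 1L)
    chars <- .sample_aa(L)
    # well-separated planting slots, clear of both termini
    slots <- seq(14L, L - 13L, by = 30L)
    k <- min(config$sequons_per_protein, length(slots))
    pos <- sort(sample(slots, k))
    is_pos <- labels[i] == "glycoprotein" & runif(k) < config$pos_fraction
    for (j in seq_len(k)) {
      p <- pos[j]
      chars[p] <- "N"
      chars[p + 1L] <- sample(setdiff(AA_STANDARD, "P"), 1L)
      chars[p + 2L] <- sample(c("S", "T"), 1L)
      for (d in seq_len(nrow(pd))) {
        rate <- min(0.95, (1 / 20) * pd$factor[d])
        q <- if (is_pos[j]) rate else 1 / 20
        fp <- if (pd$side[d] == "N_terminal") p - pd$gap[d] - 1L else p + pd$gap[d] + 1L
        if (fp < 1L || fp > L || fp %in% c(p, p + 1L, p + 2L)) next
        chars[fp] <- if (runif(1) < q) pd$residue[d] else
          sample(setdiff(AA_STANDARD, pd$residue[d]), 1L)
      }
    }
    seqs[i] <- paste(chars, collapse = "")
    if (any(is_pos)) {
      status <- rep("validated_glycosite", sum(is_pos))
      if (config$excluded_fraction > 0) {
        flip <- runif(sum(is_pos)) < config$excluded_fraction
        status[flip] <- "excluded_evidence"
      }
      ann[[length(ann) + 1L]] <- data.frame(
        protein_id = ids[i], position = pos[is_pos], status = status,
        stringsAsFactors = FALSE)
    }
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(protein_id = character(), position = integer(),
               status = character(), stringsAsFactors = FALSE)
  list(proteins = data.frame(id = ids, sequence = seqs, label = labels,
                             stringsAsFactors = FALSE),
       annotations = annotations)
}

#' Generate class-conditional SA/SS annotation strings for sequon windows
#'
#' SA classes are drawn per position from {E, B}; SS from {H, E, C}. At the
#' sequon-proximal `effect_positions`, glycosite windows favour exposure (E)
#' and coil (C) while negatives favour burial and helix, with the shift set
#' by `sa_effect` / `ss_effect`; elsewhere both classes share a uniform
#' emission. Window positions that are padding (`X` in the sequence window)
#' carry the pad character `-`.
#'
#' @param dataset Sequon-window data.frame from [build_dataset()] (columns
#'   `window`, `label`).
#' @param config A `generator_config`.
#' @return The dataset with `sa` and `ss` string columns appended.
#' @export
generate_annotated_windows <- function(dataset, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + .SEED_OFFSET[["annotations"]])
  l <- unique(nchar(dataset$window))
  stopifnot(length(l) == 1L)
  n <- nrow(dataset)
  pos_lab <- dataset$label == "positive"
  sa <- character(n); ss <- character(n)
  for (i in seq_len(n)) {
    in_eff <- seq_len(l) %in% config$effect_positions
    p_e <- ifelse(in_eff, 0.5 + if (pos_lab[i]) config$sa_effect else -config$sa_effect,
                  0.5)
    sa_i <- ifelse(runif(l) < p_e, "E", "B")
    eff <- config$ss_effect
    ss_i <- character(l)
    for (j in seq_len(l)) {
      pr <- if (!in_eff[j]) c(1, 1, 1) / 3
      else if (pos_lab[i]) c(1 / 3 - eff / 2, 1 / 3 - eff / 2, 1 / 3 + eff)
      else c(1 / 3 + eff, 1 / 3 - eff / 2, 1 / 3 - eff / 2)
      ss_i[j] <- sample(c("H", "E", "C"), 1L, prob = pr)
    }
    pad <- strsplit(dataset$window[i], "")[[1]] == "X"
    sa_i[pad] <- PAD_CHAR; ss_i[pad] <- PAD_CHAR
    sa[i] <- paste(sa_i, collapse = ""); ss[i] <- paste(ss_i, collapse = "")
  }
  dataset$sa <- sa
  dataset$ss <- ss
  dataset
}

#' Generate a homolog-set universe with class-structured overlap
#'
#' The universe of pseudo hit ids is split into a glycoprotein-associated and
#' a non-glycoprotein-associated half. Each protein's similar-protein set
#' draws a fraction `0.5 + overlap_boost / 2` of its members from its own
#' label's half, so same-label proteins share more hits. Hit probabilities
#' are uniform on [0.5, 1] (all retained by the 0.5 filter).
#'
#' @param config A `generator_config`.
#' @param protein_ids Character vector of protein ids.
#' @param labels Parallel `"glycoprotein"` / `"non_glycoprotein"` labels.
#' @param dir Optional directory: when given, one `<id>.tsv` hit-list file
#'   per protein is written (round-trippable through [parse_hit_list()]).
#' @return List with `sets` (list of `homolog_set`) and `index`
#'   (`template_index` over all proteins).
#' @export
generate_homolog_universe <- function(config, protein_ids, labels, dir = NULL) {
  stopifnot(inherits(config, "generator_config"),
            length(protein_ids) == length(labels))
  set.seed(config$seed + .SEED_OFFSET[["homologs"]])
  m <- config$universe_size
  half <- m %/% 2L
  pool <- list(
    glycoprotein = sprintf("U%04d", seq_len(half)),
    non_glycoprotein = sprintf("U%04d", (half + 1L):m))
  f_own <- 0.5 + config$overlap_boost / 2
  sets <- vector("list", length(protein_ids))
  for (i in seq_along(protein_ids)) {
    size <- max(2L, stats::rpois(1L, config$mean_set_size))
    n_own <- min(half, round(size * f_own))
    n_oth <- min(half, size - n_own)
    own <- pool[[labels[i]]]
    oth <- pool[[setdiff(names(pool), labels[i])]]
    members <- c(sample(own, n_own), sample(oth, n_oth))
    prob <- runif(length(members), 0.5, 1)
    sets[[i]] <- homolog_set(protein_ids[i], members, prob)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write.table(
        data.frame(hit_id = members, probability = round(prob, 4)),
        file.path(dir, paste0(protein_ids[i], ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  names(sets) <- protein_ids
  list(sets = sets, index = build_template_index(sets, labels))
}
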