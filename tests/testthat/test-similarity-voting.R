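test_that("parse_hit_list handles simple TSVs, thresholds and self-hits", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("hit_id\tprobability", "A\t0.99", "B\t0.49", "Q\t0.9"), f)
  hs <- parse_hit_list(f, "Q")
  expect_equal(hs$members, "A")  # B below threshold, Q is a self-hit

  # percent probabilities are normalised to [0,1]
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\t97.1", "B\t45.0"), f2)
  hs2 <- parse_hit_list(f2, "Q")
  expect_equal(unname(hs2$prob["A"]), 0.971)
  expect_false("B" %in% hs2$members)

  # profile-search summary block style: rank, id, probability, E-value...
  f3 <- withr::local_tempfile(fileext = ".hhr")
  writeLines(c(" No Hit  Prob E-value",
               "  1 P12345  99.9 1e-40",
               "  2 P67890  45.0 0.5"), f3)
  hs3 <- parse_hit_list(f3, "Q")
  expect_equal(hs3$members, "P12345")

  f4 <- withr::local_tempfile()
  writeLines("not a hit line at all", f4)
  expect_error(parse_hit_list(f4, "Q"), "line 1")
})

test_that("find_templates applies the overlap threshold with leave-self-out", {
  mk <- function(id, members) homolog_set(id, members)
  u <- paste0("U", 1:20)
  index <- build_template_index(
    list(mk("P1", u[1:6]), mk("P2", u[1:4]), mk("Q", u[1:10])),
    c("glycoprotein", "non_glycoprotein", "glycoprotein"))
  q <- mk("Q", u[1:10])
  tpl <- find_templates(q, index, k_min = 5)
  expect_equal(tpl$template_id, "P1")     # overlap 6 >= 5; P2 has 4; Q excluded
  expect_equal(tpl$overlap, 6L)
  tpl4 <- find_templates(q, index, k_min = 4)
  expect_setequal(tpl4$template_id, c("P1", "P2"))
  expect_equal(nrow(find_templates(mk("Z", character(0)), index)), 0)
})

test_that("voting_score computes squared-overlap votes", {
  q <- homolog_set("Q", paste0("U", 1:10))
  tpl <- data.frame(template_id = c("a", "b", "c"), overlap = c(6L, 5L, 5L),
                    label = c("glycoprotein", "glycoprotein", "non_glycoprotein"),
                    stringsAsFactors = FALSE)
  v <- voting_score(q, tpl)
  expect_equal(v$v_g, 61); expect_equal(v$v_ng, 25)
  expect_equal(v$score, 61 / 86)

  sym <- voting_score(q, data.frame(template_id = c("a", "b"),
                                    overlap = c(5L, 5L),
                                    label = c("glycoprotein", "non_glycoprotein")))
  expect_equal(sym$score, 0.5)

  only_g <- voting_score(q, tpl[tpl$label == "glycoprotein", ])
  expect_equal(only_g$score, 1.0)
  none <- voting_score(q, tpl[0, ])
  expect_true(is.na(none$score))

  # label swap maps score s -> 1 - s; an extra glycoprotein template
  # strictly increases the score
  swapped <- tpl
  swapped$label <- ifelse(tpl$label == "glycoprotein",
                          "non_glycoprotein", "glycoprotein")
  expect_equal(voting_score(q, swapped)$score, 1 - v$score)
  more <- rbind(tpl, data.frame(template_id = "d", overlap = 5L,
                                label = "glycoprotein"))
  expect_gt(voting_score(q, more)$score, v$score)
})

test_that("voting matches a brute-force oracle on random universes", {
  oracle_score <- function(query_members, index_sets, index_labels, k_min = 5) {
    vg <- 0; vng <- 0
    for (i in seq_along(index_sets)) {
      ov <- 0
      for (m in index_sets[[i]]) if (m %in% query_members) ov <- ov + 1
      if (ov >= k_min) {
        if (index_labels[i] == "glycoprotein") vg <- vg + ov^2
        else vng <- vng + ov^2
      }
    }
    if (vg + vng == 0) NA_real_ else vg / (vg + vng)
  }
  set.seed(47)
  u <- paste0("U", 1:40)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    sets <- lapply(seq_len(n), function(i) {
      homolog_set(paste0("P", i), sample(u, sample(5:25, 1)))
    })
    labels <- sample(c("glycoprotein", "non_glycoprotein"), n, replace = TRUE)
    index <- build_template_index(sets, labels)
    q <- homolog_set("Q", sample(u, sample(5:25, 1)))
    got <- voting_score(q, find_templates(q, index))$score
    want <- oracle_score(q$members,
                         lapply(sets, `[[`, "members"), labels)
    expect_identical(got, want)
  }
})

test_that("scoring a training protein never consults its own index entry", {
  u <- paste0("U", 1:30)
  sets <- list(homolog_set("P1", u[1:10]), homolog_set("P2", u[1:10]),
               homolog_set("P3", u[20:26]))
  index <- build_template_index(sets, c("glycoprotein", "non_glycoprotein",
                                        "non_glycoprotein"))
  # P1's only qualifying partner is P2 (overlap 10); its own entry would give
  # overlap 10 for glycoprotein and flip the score to 0.5
  s <- score_proteins(sets[1], index)
  expect_equal(unname(s), 0)
})

test_that("score_interval_summary partitions scores into the five intervals", {
  scores <- c(0.05, 0.15, 0.25, 0.45, 0.65, 0.85, 1.0, NA)
  labels <- c(rep("non_glycoprotein", 4), rep("glycoprotein", 4))
  s <- score_interval_summary(scores, labels)
  expect_equal(nrow(s), 5)
  expect_equal(sum(s$n), 7)          # NA dropped
  expect_equal(s$n, c(2L, 1L, 1L, 1L, 2L))  # 1.0 falls in the closed top bin
  expect_equal(s$p_glyco[5], 1.0)

  # strong homology structure -> glycoprotein fraction rises with score
  cfg <- generator_config(seed = 53, overlap_boost = 0.6)
  labs <- rep(c("glycoprotein", "non_glycoprotein"), each = 60)
  ids <- sprintf("P%03d", seq_along(labs))
  hom <- generate_homolog_universe(cfg, ids, labs)
  sc <- score_proteins(hom$sets, hom$index)
  tab <- score_interval_summary(sc, labs)
  p <- tab$p_glyco[!is.na(tab$p_glyco)]
  expect_true(all(diff(p) >= 0))
})

test_that("template indexes survive a TSV round-trip", {
  sets <- list(homolog_set("P1", c("U1", "U2", "U3")),
               homolog_set("P2", character(0)))
  index <- build_template_index(sets, c("glycoprotein", "non_glycoprotein"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_template_index(index, path)
  back <- read_template_index(path)
  expect_equal(names(back), names(index))
  expect_equal(back$P1$members, index$P1$members)
  expect_equal(back$P2$members, character(0))
  expect_equal(vapply(back, `[[`, character(1), "label"),
               vapply(index, `[[`, character(1), "label"))
})
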