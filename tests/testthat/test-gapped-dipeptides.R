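test_that("every valid window yields exactly 23 gapped dipeptides", {
  w <- make_window(paste0(strrep("A", 11), "W"), "G", "T")
  gds <- enumerate_window_gds(w)
  expect_length(gds, 23)
  expect_true(all(c("W0N", "N0G", "A2N", "A11N", "N11A") %in% gds))
  expect_false(any(grepl("^N1[A-Z]$", gds)))  # N1S / N1T never emitted
  # canonical order: N-terminal gaps 11..0 then C-terminal 0, 2..11
  expect_equal(gds[1], "A11N")
  expect_equal(gds[12], "W0N")
  expect_equal(gds[13], "N0G")

  allx <- paste0(strrep("X", 11), "WNGT", strrep("X", 10))
  expect_length(enumerate_window_gds(allx), 23)
  expect_error(enumerate_window_gds("NGT"), "length")

  for (w in random_windows(50, seed = 7)) {
    expect_length(enumerate_window_gds(w), 23)
  }
})

test_that("the realizable feature space has 460 types and covers all windows", {
  fs <- gd_feature_space()
  expect_equal(nrow(fs), 460)
  keys <- glysite:::.gd_key(fs$residue, fs$gap, fs$side)
  expect_equal(length(unique(keys)), 460)
  expect_equal(sum(fs$side == "C_terminal" & fs$gap == 1L), 0)

  # exhaustive oracle: keys observed across random valid windows are a
  # subset of (and at this sample size, equal to) the enumerated space;
  # N-P-S/T windows must be sampled too, else the C-terminal gap-0 proline
  # type (realizable only there) is never seen
  observed <- unique(unlist(lapply(random_windows(10000, seed = 13,
                                                  allow_p_middle = TRUE),
                                   glysite:::.window_gd_keys)))
  expect_true(all(observed %in% keys))
  expect_setequal(observed, keys)
})

test_that("fit_gdr computes the occurrence-share odds ratio", {
  # 2 positive windows both carrying W0N; 4 negatives, one carrying W0N:
  # every window contributes 23 occurrences, so shares are countable by hand
  wp <- make_window(paste0(strrep("A", 11), "W"), "G", "T")
  wn <- make_window(strrep("A", 12), "G", "T")
  tbl <- fit_gdr(c(wp, wp, wn, wn, wn, wn), c("positive", "positive",
                                              rep("negative", 4)))
  row <- tbl[tbl$gd == "W0N" & tbl$side == "N_terminal", ]
  # W0N: pos share 2/46, neg share 0 -> undefined without pseudocount? no:
  # negatives have no W0N, so gdr is NA
  expect_true(is.na(row$gdr))

  tbl2 <- fit_gdr(c(wp, wp, wn, wn), c("positive", "negative",
                                       "positive", "negative"))
  row2 <- tbl2[tbl2$gd == "W0N" & tbl2$side == "N_terminal", ]
  expect_equal(row2$gdr, (1 / 46) / (1 / 46))

  # W0N in 2/2 positives and 1/2 negatives: shares 2/46 vs 1/46 -> gdr 2
  tbl3 <- fit_gdr(c(wp, wp, wp, wn),
                  c("positive", "positive", "negative", "negative"))
  row3 <- tbl3[tbl3$gd == "W0N" & tbl3$side == "N_terminal", ]
  expect_equal(row3$gdr, 2.0)

  expect_error(fit_gdr(c(wp, wp), c("positive", "positive")), "both")
})

test_that("GDR is scale invariant and denominator-choice invariant", {
  win <- random_windows(60, seed = 21)
  lab <- rep(c("positive", "negative"), c(25, 35))
  t1 <- fit_gdr(win, lab)
  t3 <- fit_gdr(rep(win, 3), rep(lab, 3))  # tripled counts
  expect_equal(t1$gdr, t3$gdr)

  # alternative denominator: per-class window counts instead of per-class
  # occurrence totals; proportional, so normalized tables are identical
  alt_gdr <- (t1$pos_count / 25) / (t1$neg_count / 35)
  alt_gdr[t1$neg_count == 0] <- NA
  t_alt <- t1
  t_alt$gdr <- alt_gdr
  n1 <- normalize_gdr(t1)
  n2 <- normalize_gdr(t_alt)
  expect_equal(n1$normalized_gdr, n2$normalized_gdr, tolerance = 1e-12)
})

test_that("label swap maps each defined GDR to its reciprocal", {
  win <- random_windows(80, seed = 31)
  lab <- rep(c("positive", "negative"), 40)
  fwd <- fit_gdr(win, lab)
  swp <- fit_gdr(win, ifelse(lab == "positive", "negative", "positive"))
  both <- !is.na(fwd$gdr) & !is.na(swp$gdr) & fwd$gdr > 0
  expect_equal(swp$gdr[both], 1 / fwd$gdr[both], tolerance = 1e-12)
  # top- and bottom-ranked dipeptides exchange
  expect_equal(which.max(fwd$gdr[both]), which.min(swp$gdr[both]))
})

test_that("normalize_gdr rescales within each (gap, side) class", {
  win <- random_windows(40, seed = 51)
  tbl <- fit_gdr(win, rep(c("positive", "negative"), 20))
  # plant a known class: N-terminal gap 3 gets GDRs 0.5 / 1.0 / 2.5 on three
  # residues, NA elsewhere
  sel <- tbl$side == "N_terminal" & tbl$gap == 3L
  tbl$gdr[sel] <- NA
  tbl$gdr[sel][1:3] <- c(0.5, 1.0, 2.5)
  out <- normalize_gdr(tbl)
  expect_equal(out$normalized_gdr[sel][1:3], c(0.0, 0.25, 1.0))

  # degenerate class: all defined values equal -> 0.5
  sel2 <- tbl$side == "C_terminal" & tbl$gap == 5L
  tbl$gdr[sel2] <- NA
  tbl$gdr[sel2][1] <- 1.7
  out2 <- normalize_gdr(tbl)
  expect_equal(out2$normalized_gdr[sel2][1], 0.5)

  full <- normalize_gdr(fit_gdr(win, rep(c("positive", "negative"), 20)))
  expect_true(all(full$normalized_gdr >= 0 & full$normalized_gdr <= 1,
                  na.rm = TRUE))
})

test_that("encode_gd maps windows to [0,1]^23 with neutral 0.5 fallback", {
  win <- random_windows(100, seed = 61)
  tbl <- normalize_gdr(fit_gdr(win, rep(c("positive", "negative"), 50)))
  m <- encode_gd(win[1:10], tbl)
  expect_equal(dim(m), c(10L, 23L))
  expect_true(all(m >= 0 & m <= 1))

  allx <- paste0(strrep("X", 11), "WNGT", strrep("X", 10))
  mx <- encode_gd(allx, tbl)
  # X-containing dipeptides are unseen -> neutral; W0N/N0G may be learned
  expect_true(all(mx[, -c(12, 13)] == 0.5))

  expect_error(encode_gd(win[1], fit_gdr(win, rep(c("positive", "negative"), 50))),
               "normalis")
})

test_that("a dipeptide planted at 3x its negative rate ranks in the top GDR decile", {
  fix <- synthetic_dataset(seed = 17, n_glyco = 60, n_nonglyco = 60)
  tbl <- fit_gdr(fix$dataset$window, fix$dataset$label)
  defined <- !is.na(tbl$gdr)
  w5n <- which(tbl$residue == "W" & tbl$gap == 5L & tbl$side == "N_terminal")
  rank_frac <- mean(tbl$gdr[defined] <= tbl$gdr[w5n])
  expect_gte(rank_frac, 0.9)
})

test_that("GDR tables survive a TSV round-trip", {
  win <- random_windows(30, seed = 71)
  tbl <- normalize_gdr(fit_gdr(win, rep(c("positive", "negative"), 15)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gdr_table(tbl, path)
  back <- read_gdr_table(path)
  expect_equal(back$gdr, tbl$gdr)
  expect_equal(back$normalized_gdr, tbl$normalized_gdr)
  expect_equal(encode_gd(win[1:3], back), encode_gd(win[1:3], tbl))
})
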