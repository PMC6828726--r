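# Shared fixtures, generated in code. Heavy objects are built once per test
# run and cached in this environment.

`%||%` <- function(a, b) if (is.null(a)) b else a

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# a valid 25-mer sequon window from explicit flanks (11 upstream residues +
# residue adjacent to N, then X and S/T choice, then 10 downstream residues)
make_window <- function(upstream = strrep("A", 12), x = "G", st = "T",
                        downstream = strrep("A", 10)) {
  stopifnot(nchar(upstream) == 12, nchar(downstream) == 10)
  paste0(upstream, "N", x, st, downstream)
}

# n random valid sequon windows; allow_p_middle also samples N-P-S/T motifs
random_windows <- function(n, seed = NULL, allow_p_middle = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  mid_pool <- if (allow_p_middle) glysite:::AA_STANDARD else
    setdiff(glysite:::AA_STANDARD, "P")
  vapply(seq_len(n), function(i) {
    make_window(
      paste(sample(glysite:::AA_STANDARD, 12, replace = TRUE), collapse = ""),
      sample(mid_pool, 1),
      sample(c("S", "T"), 1),
      paste(sample(glysite:::AA_STANDARD, 10, replace = TRUE), collapse = ""))
  }, character(1))
}

# random SA / SS annotation strings
random_sa <- function(n, l = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("E", "B"), l, replace = TRUE), collapse = ""), character(1))
}

random_ss <- function(n, l = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("H", "E", "C"), l, replace = TRUE), collapse = ""), character(1))
}

# full annotated synthetic dataset under the default study conditions
synthetic_dataset <- function(seed, n_glyco = 40, n_nonglyco = 40, ...) {
  cfg <- generator_config(seed = seed, n_glycoproteins = n_glyco,
                          n_non_glycoproteins = n_nonglyco, ...)
  gen <- generate_proteins(cfg)
  ds <- generate_annotated_windows(build_dataset(gen$proteins, gen$annotations), cfg)
  list(config = cfg, proteins = gen$proteins, annotations = gen$annotations,
       dataset = ds)
}

# small hyperparameter grid used throughout the simulation studies
COARSE_C <- 2^c(-1, 3, 7)
COARSE_GAMMA <- 2^c(-7, -3, 1)
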