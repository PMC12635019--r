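# Shared fixtures, built in code at test time.

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny beta matrix with explicit values.
tiny_beta <- function(values, sample_ids = NULL, cpg_ids = NULL) {
  m <- as.matrix(values)
  if (!is.null(sample_ids)) rownames(m) <- sample_ids
  if (!is.null(cpg_ids)) colnames(m) <- cpg_ids
  beta_matrix(m)
}

tiny_metadata <- function(n, ages = seq(25, length.out = n, by = 5),
                          status = rep("healthy", n)) {
  data.frame(sample_id = paste0("sample", seq_len(n)), age = ages,
             status = status, stringsAsFactors = FALSE)
}

# A small mixed cohort reused across audit tests.
small_cohort <- function(n = 300, seed = 42, ...) {
  suppressWarnings(generate_cohort(
    inflammaging_cohort_spec(n_samples = n, seed = seed, ...)))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

expect_simplex <- function(fr, tol = 1e-9) {
  expect_true(all(fr >= -tol))
  expect_true(all(abs(rowSums(fr) - 1) < tol))
}
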