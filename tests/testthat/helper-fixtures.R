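# Small in-code fixtures shared across test files.

tiny_expr <- function(n_genes = 5, n_samples = 6, scale = "log2",
                      seed = 11) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * n_samples, 5, 1), n_genes, n_samples,
                 dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                 sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(vals, scale = scale)
}

tiny_samples <- function(ids, ages = NULL, ...) {
  n <- length(ids)
  sample_table(data.frame(sample_id = ids,
                          age = if (is.null(ages)) seq(41, 68,
                                                       length.out = n)
                                else ages,
                          ...,
                          stringsAsFactors = FALSE))
}

# Call table with given calls, for set-level operations.
fake_calls <- function(genes, call, tissue = "t") {
  out <- data.frame(gene = genes, r = ifelse(call == "down", -0.5,
                                             ifelse(call == "up", 0.5, 0)),
                    p = ifelse(call == "none", 0.5, 1e-4),
                    n = 100L, call = call, stringsAsFactors = FALSE)
  attr(out, "tissue") <- tissue
  class(out) <- c("AgingCallTable", "data.frame")
  out
}

# Upper-tail hypergeometric probability by exhaustive enumeration over
# the support (independent oracle for the enrichment module).
enum_hyper_upper <- function(k, K, n, N) {
  js <- max(0, n - (N - K)):min(n, K)
  js <- js[js >= k]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
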