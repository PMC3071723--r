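# Independent oracles, deliberately naive: direct factorial arithmetic on
# small integers, no calls into the package or into dbinom/pbinom.

# binomial coefficient by cumulative product
brute_choose <- function(n, k) {
  if (k == 0 || k == n) return(1)
  prod((n - k + 1):n) / prod(1:k)
}

# conditional mass of y reads in library B given x in A, via the
# (N_B/N_A)-ratio form evaluated with plain products
brute_mass <- function(x, y, n_a, n_b) {
  r <- n_b / n_a
  brute_choose(x + y, y) * r^y / (1 + r)^(x + y)
}

brute_pvalue <- function(x, y, n_a, n_b, two_sided = TRUE) {
  t <- x + y
  masses <- vapply(0:t, function(k) brute_mass(t - k, k, n_a, n_b), numeric(1))
  lower <- sum(masses[seq_len(y + 1)])          # P(Y <= y)
  upper <- sum(masses[(y + 1):(t + 1)])         # P(Y >= y)
  smaller <- min(lower, upper)
  if (two_sided) min(1, 2 * smaller) else smaller
}

# pooled two-sample Student t, written out from the textbook formula
brute_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# small well-formed count table used across io/pipeline tests
make_count_fixture <- function(path, rows = NULL) {
  if (is.null(rows))
    rows <- c("c1\t3\t2", "c2\t0\t5", "c3\t7\t0", "c4\t1\t1", "c5\t0\t9")
  writeLines(c("contig_id\tcount_a\tcount_b", rows), path)
  path
}

# qPCR fixture: two groups x n replicates, one gene, planted dCT separation
make_ct_fixture <- function(gene = "vitellogenin_a", sep_cycles = 5,
                            n = 4, noise = 0.05, seed = 42) {
  set.seed(seed)
  grp <- rep(c("female", "male"), each = n)
  ids <- paste0(grp, seq_len(n))
  dct <- ifelse(grp == "female", 20 - sep_cycles, 20) + rnorm(2 * n, 0, noise)
  data.frame(sample_id = ids, group = grp, gene = gene,
             replicate = rep(seq_len(n), 2),
             ct_target = 10 + dct, ct_reference = 10,
             stringsAsFactors = FALSE)
}
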