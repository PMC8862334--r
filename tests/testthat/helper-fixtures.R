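# Small in-code fixtures shared across tests.

# character matrix from a vector of equal-length strings
seq_matrix <- function(...) {
  s <- c(...)
  m <- t(vapply(s, function(x) strsplit(x, "")[[1]], character(nchar(s[1]))))
  rownames(m) <- names(s)
  m
}

# the worked micro-example pair: A = {AAAA, AAAT}, B = {AATT, AATT}
micro_pair_ds <- function() {
  multilocus_dataset(
    list(L1 = seq_matrix(a1 = "AAAA", a2 = "AAAT", b1 = "AATT", b2 = "AATT")),
    data.frame(sample = c("a1", "a2", "b1", "b2"),
               population = c("A", "A", "B", "B"),
               locality = c("l1", "l1", "l2", "l2")))
}

# random two-population dataset on the full A/C/G/T/N/- alphabet
random_pair_ds <- function(seed, max_seq = 6L, max_len = 60L, n_loci = 2L,
                           miss_rate = 0.12) {
  set.seed(seed)
  nA <- sample(1:(max_seq - 1L), 1L)
  nB <- sample(1:(max_seq - nA), 1L)
  loci <- lapply(seq_len(n_loci), function(i) {
    L <- sample(4:max_len, 1L)
    m <- matrix(sample(c("A", "C", "G", "T"), (nA + nB) * L, replace = TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)),
                nA + nB, L)
    miss <- matrix(runif((nA + nB) * L) < miss_rate, nA + nB, L)
    m[miss] <- sample(c("N", "-"), sum(miss), replace = TRUE)
    rownames(m) <- c(paste0("a", seq_len(nA)), paste0("b", seq_len(nB)))
    m
  })
  names(loci) <- paste0("L", seq_len(n_loci))
  multilocus_dataset(
    loci,
    data.frame(sample = c(paste0("a", seq_len(nA)), paste0("b", seq_len(nB))),
               population = rep(c("A", "B"), c(nA, nB)),
               locality = rep(c("l1", "l2"), c(nA, nB))))
}
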