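# Shared fixture builders.  Everything is generated in code; no stored data.

# Tiny annotated count matrix: 4 biological features (2 miRNA, 1 snoRNA,
# 1 tRNA) + 2 calibrators, 3 samples.
toy_counts <- function() {
  m <- rbind(`miR-a` = c(10, 20, 30),
             `miR-b` = c(5, 0, 15),
             `sno-a` = c(80, 60, 50),
             `trna-a` = c(5, 20, 5),
             `cal-1` = c(100, 200, 100),
             `cal-2` = c(400, 800, 400))
  colnames(m) <- c("s1", "s2", "s3")
  count_matrix(m, c("miRNA", "miRNA", "snoRNA", "tRNA", "other", "other"),
               c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
}

# Small cohort config sized for fast tests.
small_config <- function(seed = 1L, ...) {
  defaults <- list(n_patients_discovery = 12L, n_patients_validation = 0L,
                   n_controls = 6L, n_mirna = 60L,
                   n_other_ncrna = c(snoRNA = 15L, tRNA = 10L, scRNA = 5L,
                                     other = 10L),
                   n_genes = 120L, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Deterministic NB count fixture for DE engine tests.
nb_fixture <- function(seed = 42L, G = 300L, n = 16L, planted = 0L,
                       log2fc = 2, phi = 0.2) {
  withr::with_seed(seed, {
    mu <- exp(rnorm(G, 5, 1.5))
    grp <- rep(0:1, each = n / 2)
    mum <- matrix(mu, G, n)
    if (planted > 0) mum[seq_len(planted), grp == 1] <-
        mum[seq_len(planted), grp == 1] * 2^log2fc
    counts <- matrix(rnbinom(G * n, mu = mum, size = 1 / phi), G,
                     dimnames = list(sprintf("f%03d", 1:G), paste0("s", 1:n)))
    list(counts = count_matrix(counts, rep("miRNA", G)),
         design = cbind(`(Intercept)` = 1, group = grp),
         group = grp)
  })
}

# Hand-rollable survival toy: two groups, known event pattern.
toy_surv <- function() {
  data.frame(patient_id = paste0("p", 1:4),
             time_months = c(1, 2, 3, 4),
             event = c(TRUE, TRUE, TRUE, TRUE),
             group = c("A", "A", "B", "B"),
             stringsAsFactors = FALSE)
}
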