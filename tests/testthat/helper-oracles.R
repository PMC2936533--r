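# Independent oracles, deliberately implemented differently from the package.

# Brute-force fate distribution for one meiosis + intra-tetrad mating:
# enumerate carrier placements as 0/1 indicator vectors over the four spores
# (spores 1,2 MATa; 3,4 MATalpha) and average over every legal mating.
# Inter-spore matings are enumerated as all unordered pairs of distinct
# spores with opposite mating type.
brute_mode_probs <- function(carriers, mode) {
  grid <- expand.grid(s1 = 0:1, s2 = 0:1, s3 = 0:1, s4 = 0:1)
  grid <- grid[rowSums(grid) == carriers, , drop = FALSE]
  out <- c(fixed = 0, heterozygous = 0, lost = 0)
  nconf <- 0L
  for (i in seq_len(nrow(grid))) {
    ind <- as.integer(grid[i, ])
    if (mode == "self") {
      for (k in 1:4) {
        cls <- if (ind[k] == 1L) "fixed" else "lost"
        out[cls] <- out[cls] + 1
        nconf <- nconf + 1L
      }
    } else {
      for (a in 1:2) for (b in 3:4) {
        ncar <- ind[a] + ind[b]
        cls <- c("lost", "heterozygous", "fixed")[ncar + 1L]
        out[cls] <- out[cls] + 1
        nconf <- nconf + 1L
      }
    }
  }
  out / nconf
}

brute_fate_probs <- function(carriers, s) {
  (1 - s) * brute_mode_probs(carriers, "inter_spore") +
    s * brute_mode_probs(carriers, "self")
}

# Closed-form expectation oracle for the bottleneck simulator. A mutation's
# survival probability per meiosis as a heterozygote is pH = (1-s)*2/3, and a
# resolved 2:2 mutation fixes or is lost with equal odds. Mutations arising in
# the mitotic phase of bottleneck b (or before replication of meiosis b) face
# nB - b + 1 meioses; post-replication mutations are resolved once with
# carriage-1 probabilities and face nB - b further meioses if they survive.
expected_final_counts <- function(m, G, dpb, nB, s, mult = 0,
                                  scenario = "pre_replication") {
  pH <- (1 - s) * 2 / 3
  lam_mito <- dpb * m * G
  lam_mu <- mult * m * G
  b <- seq_len(nB)
  remaining <- nB - b + 1L
  hom <- lam_mito * sum((1 - pH^remaining) / 2)
  het <- lam_mito * sum(pH^remaining)
  if (scenario == "pre_replication") {
    hom <- hom + lam_mu * sum((1 - pH^remaining) / 2)
    het <- het + lam_mu * sum(pH^remaining)
  } else if (scenario == "post_replication") {
    pF1 <- s / 4
    pH1 <- (1 - s) / 2
    hom <- hom + lam_mu * sum(pF1 + pH1 * (1 - pH^(nB - b)) / 2)
    het <- het + lam_mu * sum(pH1 * pH^(nB - b))
  }
  c(hom = hom, het = het)
}

extfile <- function(name) system.file("extdata", name, package = "tetradMA")
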