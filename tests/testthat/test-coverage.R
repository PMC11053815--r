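test_that("single-allele analytic case: coverage 0.75, average 0.75, PC90 0.4", {
  pairs <- toy_pairs("AAAAAAAAA", "X")
  freqs <- toy_freqs("X", 0.5)
  d <- hit_distribution(pairs, freqs, "World")
  expect_equal(d$pmf, c(0.25, 0.75), tolerance = 1e-15)
  m <- coverage_metrics(d)
  expect_equal(m$coverage, 0.75, tolerance = 1e-15)
  expect_equal(m$average_hit, 0.75, tolerance = 1e-15)
  expect_equal(m$pc90, 0.4, tolerance = 1e-15)
})

test_that("hits count per epitope-allele pair, presence-based", {
  pairs <- toy_pairs(c("AAAAAAAAA", "CCCCCCCCC"), c("X", "X"))
  freqs <- toy_freqs("X", 0.5)
  d <- hit_distribution(pairs, freqs, "World")
  expect_equal(d$pmf, c(0.25, 0, 0.75), tolerance = 1e-15)
  # dosage mode: the homozygote XX (p = 0.25) scores 4, heterozygote 2
  dd <- hit_distribution(pairs, freqs, "World", dosage = TRUE)
  expect_equal(dd$pmf[5], 0.25, tolerance = 1e-15)
  expect_equal(dd$pmf[3], 0.5, tolerance = 1e-15)
})

test_that("no pairs give a point mass at zero with PC90 0", {
  d <- hit_distribution(toy_pairs(character(0), character(0)),
                        toy_freqs("X", 0.5), "World")
  expect_equal(d$pmf, 1)
  m <- coverage_metrics(d)
  expect_equal(m$coverage, 0)
  expect_equal(m$average_hit, 0)
  expect_equal(m$pc90, 0)
})

test_that("PC90 crosses exactly at integer survivor values", {
  # S(1) = 1 (everyone has >= 1 hit), S(2) = 0.9 -> PC90 = 2.0
  d <- structure(list(pmf = c(0, 0.1, 0.9), region = "World"),
                 class = "hit_distribution")
  expect_equal(coverage_metrics(d)$pc90, 2.0)
  # PC90 < 1 iff coverage < 0.9
  d2 <- structure(list(pmf = c(0.05, 0.95), region = "World"),
                  class = "hit_distribution")
  m2 <- coverage_metrics(d2)
  expect_gte(m2$pc90, 1)
  d3 <- structure(list(pmf = c(0.2, 0.8), region = "World"),
                  class = "hit_distribution")
  expect_lt(coverage_metrics(d3)$pc90, 1)
})

test_that("convolution equals joint genotype enumeration on small instances", {
  set.seed(211)
  for (rep in 1:25) {
    n_loci <- sample(1:3, 1)
    loci <- list()
    freq_rows <- list()
    pair_rows <- list()
    for (li in seq_len(n_loci)) {
      n_all <- sample(1:4, 1)
      alleles <- paste0("L", li, "_", seq_len(n_all))
      f <- runif(n_all); f <- f / sum(f) * runif(1, 0.5, 1)
      hits <- sample(0:3, n_all, replace = TRUE)
      loci[[li]] <- list(freq = setNames(f, alleles),
                         hits = setNames(hits, alleles))
      freq_rows[[li]] <- data.frame(region = "World",
                                    locus = paste0("LOC", li),
                                    allele = alleles, frequency = f)
      for (ai in seq_len(n_all)) {
        if (hits[ai] > 0) {
          pair_rows[[length(pair_rows) + 1]] <- data.frame(
            mutant_sequence = paste0("PEP", li, ai, "_", seq_len(hits[ai])),
            allele = alleles[ai], locus = paste0("LOC", li),
            mhc_class = "I", stringsAsFactors = FALSE)
        }
      }
    }
    freqs <- do.call(rbind, freq_rows)
    pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
      toy_pairs(character(0), character(0))
    got <- hit_distribution(pairs, freqs, "World")$pmf
    want <- oracle_hit_pmf(loci)
    want <- want[seq_len(max(which(want > 0), 1))]
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("pairs on untyped alleles are excluded and reported", {
  pairs <- toy_pairs(c("AAAAAAAAA", "CCCCCCCCC"), c("X", "UNTYPED"))
  freqs <- toy_freqs("X", 0.5)
  d <- hit_distribution(pairs, freqs, "World")
  expect_equal(d$n_pairs_used, 1L)
  expect_equal(d$excluded$allele, "UNTYPED")
  expect_error(hit_distribution(pairs, freqs, "Atlantis"), "unknown region")
})

test_that("coverage is monotone in added pairs; averages add over disjoint alleles", {
  freqs <- rbind(toy_freqs(c("X", "Y"), c(0.3, 0.4)))
  p1 <- toy_pairs("AAAAAAAAA", "X")
  p2 <- rbind(p1, toy_pairs("CCCCCCCCC", "Y"))
  c1 <- coverage_metrics(hit_distribution(p1, freqs, "World"))
  c2 <- coverage_metrics(hit_distribution(p2, freqs, "World"))
  expect_gte(c2$coverage, c1$coverage)
  only_y <- coverage_metrics(hit_distribution(toy_pairs("CCCCCCCCC", "Y"),
                                              freqs, "World"))
  expect_equal(c2$average_hit, c1$average_hit + only_y$average_hit,
               tolerance = 1e-12)
})

test_that("regional summary averages regions, keeping World separate", {
  freqs <- rbind(toy_freqs("X", 0.5, "World"),
                 toy_freqs("X", 0.5, "RegionA"),
                 toy_freqs("X", 0.2, "RegionB"))
  pairs <- toy_pairs("AAAAAAAAA", "X")
  s <- regional_summary(pairs, freqs)
  expect_equal(nrow(s$per_region), 3L)
  covA <- s$per_region$coverage[s$per_region$region == "RegionA"]
  covB <- s$per_region$coverage[s$per_region$region == "RegionB"]
  expect_equal(s$average_regional_coverage, mean(c(covA, covB)))
  one <- regional_summary(pairs, freqs, regions = "RegionA")
  expect_equal(one$average_regional_coverage, covA)
})

test_that("minimal set cover prefers covering sets and equals the exhaustive optimum", {
  expect_identical(min_set_cover(list("A", "B", c("A", "B"))), 3L)
  # all sets identical: deterministic tie-break picks the highest score
  idx <- min_set_cover(list("A", "A", "A"), scores = c(1, 5, 2),
                       labels = c("a", "b", "c"))
  expect_identical(idx, 2L)
  expect_identical(min_set_cover(list()), integer(0))

  set.seed(223)
  for (rep in 1:40) {
    n_sets <- sample(3:10, 1)
    n_all <- sample(2:8, 1)
    sets <- lapply(seq_len(n_sets), function(i) {
      sample(paste0("a", seq_len(n_all)), sample(1:min(3, n_all), 1))
    })
    chosen <- min_set_cover(sets)
    expect_equal(sort(unique(unlist(sets[chosen]))),
                 sort(unique(unlist(sets))))
    expect_equal(length(chosen), oracle_min_cover_size(sets))
  }
})

test_that("optimized pair sets preserve coverage with fewer pairs", {
  set.seed(227)
  freqs <- toy_freqs(paste0("X", 1:6), rep(0.12, 6))
  for (rep in 1:20) {
    n <- sample(4:15, 1)
    pairs <- toy_pairs(replicate(n, random_peptide(9)),
                       sample(paste0("X", 1:6), n, replace = TRUE))
    pairs$score <- round(runif(n), 3)
    opt <- optimize_minimal_set(pairs, freqs, "World")
    expect_equal(sort(unique(opt$allele)), sort(unique(pairs$allele)))
    expect_equal(nrow(opt), length(unique(pairs$allele)))
    full_cov <- coverage_metrics(hit_distribution(pairs, freqs, "World"))
    opt_cov <- coverage_metrics(hit_distribution(opt, freqs, "World"))
    expect_equal(opt_cov$coverage, full_cov$coverage, tolerance = 1e-12)
  }
  # same-allele tie-break: highest score wins
  p <- toy_pairs(c("CCCCCCCCC", "AAAAAAAAA"), c("X1", "X1"))
  p$score <- c(0.9, 0.1)
  opt <- optimize_minimal_set(p, freqs, "World")
  expect_equal(opt$mutant_sequence, "CCCCCCCCC")
})

test_that("stepwise filtering reports coverage after each cumulative rule", {
  freqs <- toy_freqs(c("X", "Y"), c(0.4, 0.4))
  pairs <- rbind(toy_pairs("AAAAAAAAA", "X"), toy_pairs("CCCCCCCCC", "Y"))
  pairs$toxicity_label <- c("Non-Toxin", "Non-Toxin")
  pairs$half_life_hours <- c(4, 4)
  pairs$instability_index <- c(10, 10)
  pairs$allergenicity_label <- "Probable Non-Allergen"
  pairs$id_label <- 1L

  tab <- stepwise_filter_coverage(pairs, freqs, default_filter_rules("I"),
                                  "World")
  expect_equal(nrow(tab), 6L)  # step 0 + 5 rules
  expect_true(all(tab$coverage == tab$coverage[1]))
  expect_false(any(tab$coverage_reduced))

  # drop the only pair on allele Y -> flagged at the tripping rule
  pairs2 <- pairs; pairs2$toxicity_label[2] <- "Toxin"
  tab2 <- stepwise_filter_coverage(pairs2, freqs, default_filter_rules("I"),
                                   "World")
  expect_true(tab2$coverage_reduced[tab2$rule == "toxicity"])
  expect_lt(tab2$coverage[6], tab2$coverage[1])
})

test_that("frequency tables are validated", {
  expect_error(allele_frequency_table(data.frame(region = "W")), "columns")
  bad <- toy_freqs(c("X", "Y"), c(0.7, 0.5))
  expect_error(allele_frequency_table(bad), "sum to > 1")
  neg <- toy_freqs("X", -0.1)
  expect_error(allele_frequency_table(neg), "negative")
})
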