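mont20 <- montage_adjacency(20)

test_that("the default montage graph is symmetric, irreflexive, and connected", {
  m <- montage_adjacency(60)
  expect_false(any(m$edges$from == m$edges$to))
  g <- igraph::graph_from_data_frame(m$edges, directed = FALSE,
                                     vertices = data.frame(name = m$names))
  expect_equal(igraph::components(g)$no, 1)
  # every electrode has at least one neighbor
  expect_true(all(m$names %in% c(m$edges$from, m$edges$to)))
})

test_that("a disconnected explicit edge list triggers a warning", {
  expect_warning(
    montage_adjacency(4, positions = cbind(1:4, 0),
                      edges = data.frame(from = "E01", to = "E02")),
    "disconnected"
  )
})

test_that("identical conditions produce no suprathreshold electrodes", {
  dat <- make_cluster_data(10, mont20, seed = 1)
  dat2 <- dplyr::bind_rows(
    dplyr::mutate(dat, condition = "A", value = 5 + diff / 2),
    dplyr::mutate(dat, condition = "B", value = 5 + diff / 2)
  )
  dat2$diff <- NULL
  ct <- cluster_permutation_test(dat2, mont20, stat = "F", seed = 2)
  expect_equal(nrow(ct$clusters), 0)
  expect_false(any(ct$electrode_stats$suprathreshold))
})

test_that("a strong localized effect is found as a cluster of the right electrodes", {
  adj <- aperiodic:::adjacency_index(mont20)
  i5 <- match("E05", mont20$names)
  target <- mont20$names[sort(c(i5, adj[[i5]]))]
  found <- vapply(1:10, function(seed) {
    dat <- make_cluster_data(25, mont20, effect = 3, effect_electrodes = target,
                             sd = 1, seed = seed)
    ct <- cluster_permutation_test(dat, mont20, stat = "paired_t",
                                   n_perm = 500, seed = seed + 100)
    sig <- ct$clusters[ct$clusters$significant, ]
    if (nrow(sig) == 0) return(FALSE)
    hit <- unlist(sig$electrodes)
    setequal(hit, target)
  }, logical(1))
  expect_gte(mean(found), 0.9)
})

test_that("an injected positive effect yields positive-sign clusters only", {
  dat <- make_cluster_data(25, mont20, effect = 2,
                           effect_electrodes = mont20$names, seed = 3)
  ct <- cluster_permutation_test(dat, mont20, stat = "paired_t", seed = 4)
  expect_true(nrow(ct$clusters) > 0)
  expect_true(all(ct$clusters$sign == "positive"))
})

test_that("p-values respect the Monte-Carlo floor and clusters are connected", {
  dat <- make_cluster_data(25, mont20, effect = 2,
                           effect_electrodes = mont20$names, seed = 5)
  ct <- cluster_permutation_test(dat, mont20, stat = "F", n_perm = 200, seed = 6)
  expect_true(all(ct$clusters$p_value >= 1 / (200 + 1)))
  adj <- aperiodic:::adjacency_index(mont20)
  for (el in ct$clusters$electrodes) {
    idx <- match(el, mont20$names)
    expect_equal(length(aperiodic:::connected_groups(idx, adj)), 1)
  }
})

test_that("stricter sample thresholds shrink the suprathreshold set", {
  dat <- make_cluster_data(25, mont20, effect = 1,
                           effect_electrodes = mont20$names, seed = 7)
  loose <- cluster_permutation_test(dat, mont20, stat = "F",
                                    sample_alpha = 0.05, n_perm = 100, seed = 8)
  strict <- cluster_permutation_test(dat, mont20, stat = "F",
                                     sample_alpha = 0.001, n_perm = 100, seed = 8)
  loose_set <- loose$electrode_stats$electrode[loose$electrode_stats$suprathreshold]
  strict_set <- strict$electrode_stats$electrode[strict$electrode_stats$suprathreshold]
  expect_true(all(strict_set %in% loose_set))
  expect_lte(sum(purrr::map_dbl(strict$clusters$mass, abs)),
             sum(purrr::map_dbl(loose$clusters$mass, abs)) + 1e-12)
})

test_that("detection probability is non-decreasing in effect size", {
  rate <- vapply(c(0.3, 0.8, 2), function(eff) {
    mean(vapply(1:6, function(seed) {
      dat <- make_cluster_data(20, mont20, effect = eff,
                               effect_electrodes = mont20$names[1:6],
                               seed = seed * 13)
      ct <- cluster_permutation_test(dat, mont20, stat = "paired_t",
                                     n_perm = 300, seed = seed)
      any(ct$clusters$significant)
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
})

test_that("degenerate inputs raise errors", {
  dat <- make_cluster_data(1, mont20, seed = 9)
  expect_error(cluster_permutation_test(dat, mont20),
               class = "aperiodic_input_error")
  bad <- make_cluster_data(5, mont20, seed = 10)
  bad$electrode[1] <- "NOPE"
  expect_error(cluster_permutation_test(bad, mont20),
               class = "aperiodic_input_error")
})

test_that("drug-contrast maps run per condition-period with correct signs", {
  tbl <- make_exponent_table(n_subjects = 15, n_electrodes = 8,
                             effect_drug = 0.3, noise_sd = 0.05, seed = 11)
  m8 <- montage_adjacency(8)
  res <- electrodewise_condition_tests(tbl, m8, n_perm = 200, seed = 12)
  expect_equal(nrow(res), 8)  # 4 conditions x 2 periods
  expect_true(all(res$n_significant >= 1))
  allsigns <- unlist(purrr::map(res$test, ~ .x$clusters$sign))
  expect_true(all(allsigns == "positive"))
})
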