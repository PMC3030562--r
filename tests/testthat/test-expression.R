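design <- sample_design()

toy_detection <- function() {
  tibble::tibble(
    probe_id = c("p1", "p2", "p3"),
    s1 = c(0.5, 0.005, 0.005),
    s2 = c(0.005, 0.005, 0.02))
}

test_that("detection filter keeps probes detected in at least one sample", {
  det <- detection_filter(toy_detection(), threshold = 0.01)
  expect_equal(det$expressed, c(TRUE, FALSE, TRUE))
  expect_equal(det$n_detected, c(1L, 0L, 1L))
  # inverted chip convention: detected = small detection p-value
  det_inv <- detection_filter(toy_detection(), threshold = 0.01,
                              direction = "less")
  expect_equal(det_inv$expressed, c(TRUE, TRUE, TRUE))
})

test_that("moderated DE calls planted effects and reduces to BH on one probe", {
  sim <- simulate_expression(design, n_probes = 1, n_de_per_transition = 0,
                             seed = 90)
  one <- moderated_de(sim$exprs, sim$samples,
                      list(name = "t", from = "WT", to = "FDCP"),
                      prior_df = 0)
  expect_equal(one$adj_p, one$p)

  expect_error(moderated_de(sim$exprs, sim$samples,
                            list(name = "t", from = "WT", to = "XX")),
               "not present")
})

test_that("all-null expression data produce essentially no calls at FDR 0.001", {
  runs_with_calls <- 0L
  for (seed in 1:100) {
    sim <- simulate_expression(design, n_probes = 1500,
                               n_de_per_transition = 0, seed = 100 + seed)
    de <- moderated_de(sim$exprs, sim$samples,
                       list(name = "init", from = "FDCP", to = "ME-I"))
    if (any(de$call != "ns")) runs_with_calls <- runs_with_calls + 1L
  }
  expect_lte(runs_with_calls, 5L)
})

test_that("planted four-sigma effects are recovered with controlled FDP", {
  # 500 DE probes of 10,000 at log-fc = 4 * noise_sd, n = 3 per condition
  d2 <- sample_design(conditions = c("c1", "c2"), group_b = "c2")
  tr <- tibble::tibble(name = "t", from = "c1", to = "c2")
  sim <- simulate_expression(d2, n_probes = 10000,
                             n_de_per_transition = 500,
                             log_fc = 2, noise_sd = 0.5,
                             detection_fraction = 1,
                             transitions = tr, seed = 91)
  de <- moderated_de(sim$exprs, sim$samples, as.list(tr[1, ]))
  truth <- sim$truth$labels
  m <- dplyr::left_join(de, truth, by = "probe_id")
  sens <- mean(m$call[m$label != "null"] != "ns")
  called <- sum(m$call != "ns")
  fdp <- sum(m$label == "null" & m$call != "ns") / max(1, called)
  # sensitivity bound frozen from the recorded-seed oracle run: a 4-sigma
  # shift with n = 3 and df = nA + nB - 2 + 2*prior_df = 24 yields ~0.36
  # power at BH FDR 0.001 (an adaptive-df moderated test reaches ~0.8 on
  # the same data, but this package fixes the df formula above)
  expect_gte(sens, 0.35)
  expect_lte(fdp, 0.05)
  # direction agreement among true positives
  tp <- m[m$label != "null" & m$call != "ns", ]
  expect_true(all(tp$call == tp$label))
})

test_that("non-redundant DE is the union over transitions", {
  de <- tibble::tibble(
    probe_id = c("a", "b", "c", "d", "b", "e", "f", "g"),
    transition = rep(c("t1", "t2"), each = 4),
    call = c("up", "up", "down", "ns", "up", "up", "down", "up"))
  nr <- nonredundant_de(de)
  expect_equal(nrow(nr), 6)                      # union, d is ns
  expect_equal(nr$n_transitions[nr$probe_id == "b"], 2)
  expect_match(nr$calls[nr$probe_id == "b"], "t1:up;t2:up")
  expect_equal(nrow(nonredundant_de(de[de$call == "ns", ])), 0)
})

test_that("shared progression sets are direction-matched intersections", {
  de_a <- tibble::tibble(probe_id = c("A", "B", "C"),
                         call = c("up", "up", "down"))
  de_b <- tibble::tibble(probe_id = c("B", "D", "C", "E"),
                         call = c("up", "up", "down", "down"))
  sh <- shared_progression_sets(de_a, de_b)
  expect_equal(sh$probe_id[sh$direction == "up"], "B")
  expect_equal(sh$probe_id[sh$direction == "down"], "C")
  # disjoint call sets -> both empty
  sh2 <- shared_progression_sets(
    tibble::tibble(probe_id = "X", call = "up"),
    tibble::tibble(probe_id = "Y", call = "up"))
  expect_equal(nrow(sh2), 0)
  # discordant direction excluded
  sh3 <- shared_progression_sets(
    tibble::tibble(probe_id = "Z", call = "up"),
    tibble::tibble(probe_id = "Z", call = "down"))
  expect_equal(nrow(sh3), 0)
})

test_that("reversing a comparison swaps up and down calls", {
  sim <- simulate_expression(design, n_probes = 3000,
                             n_de_per_transition = 150, seed = 92)
  fwd <- moderated_de(sim$exprs, sim$samples,
                      list(name = "f", from = "FDCP", to = "ME-I"))
  rev <- moderated_de(sim$exprs, sim$samples,
                      list(name = "r", from = "ME-I", to = "FDCP"))
  expect_equal(rev$log_fc, -fwd$log_fc)
  expect_equal(rev$p, fwd$p)
  map <- c(up = "down", down = "up", ns = "ns")
  expect_equal(rev$call, unname(map[fwd$call]))
})

test_that("BH adjustment is monotone in the raw p-value rank", {
  sim <- simulate_expression(design, n_probes = 2000,
                             n_de_per_transition = 100, seed = 93)
  de <- moderated_de(sim$exprs, sim$samples,
                     list(name = "t", from = "FDCP", to = "ME-I"))
  ord <- order(de$p)
  expect_true(all(diff(de$adj_p[ord]) >= -1e-15))
})

test_that("probe sets collapse to genes through a mapping table", {
  sets <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                         direction = c("up", "up", "down"))
  map <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                        gene = c("G1", "G1", "G2"))
  genes <- collapse_to_genes(sets, map)
  expect_equal(nrow(genes), 2)
  expect_equal(genes$gene, c("G1", "G2"))
})
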