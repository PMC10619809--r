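# IIT 3.0 engine: repertoires, EMD, mechanism phi, big Phi, complexes.
# The engine is checked against hand computations, stored oracle values
# and a live naive exhaustive reference (helper-oracle.R).

test_that("conditioning clamps background and preserves determinism", {
  # copy chain: node 2 copies node 1; clamp node 1 on
  net <- logic_network(list(NULL, list(inputs = 1L, table = c(0L, 1L))))
  tp <- condition_tpm(full_tpm(net), 2L, c(1L, 1L))
  expect_equal(tp$n, 1L)
  expect_equal(unname(tp$probs[, 1L]), c(1, 1)) # next state always on
  # clamp node 1 off: next state always off
  tp0 <- condition_tpm(full_tpm(net), 2L, c(0L, 1L))
  expect_equal(unname(tp0$probs[, 1L]), c(0, 0))
  # full-system candidate leaves the TPM unchanged
  ftpm <- full_tpm(net)
  expect_equal(condition_tpm(ftpm, 1:2, c(0L, 0L))$probs, ftpm$probs)
  # rows of deterministic conditioned TPMs stay 0/1
  b <- random_test_brain(2)
  ctp <- condition_tpm(full_tpm(b), 3:8, rep(0L, 8))
  expect_true(all(ctp$probs %in% c(0, 1)))
  # a state vector of the wrong length is rejected (a scalar would be
  # read as a state index)
  expect_error(condition_tpm(ftpm, 1:2, c(1L, 0L, 1L)), "state must")
})

test_that("repertoires match hand computations and normalize", {
  net <- logic_network(list(NULL, list(inputs = 1L, table = c(0L, 1L))))
  tp <- condition_tpm(full_tpm(net), 1:2, c(1L, 1L))
  # B := copy(A), B on, purview {A}: point mass on A = on
  expect_equal(cause_repertoire(tp, 2L, 1L, c(1L, 1L))$p, c(0, 1))
  # forward: A on, purview {B}: point mass on B = on
  expect_equal(effect_repertoire(tp, 1L, 2L, c(1L, 1L))$p, c(0, 1))
  # empty mechanism: uniform cause repertoire
  expect_equal(cause_repertoire(tp, integer(0), 1:2, c(1L, 1L))$p,
               rep(0.25, 4))
  # unreachable mechanism state flags unconstrained-by-convention
  netc <- logic_network(list(list(inputs = 1L, table = c(1L, 1L))))
  tpc <- condition_tpm(full_tpm(netc), 1L, c(0L))
  cr <- cause_repertoire(tpc, 1L, 1L, c(0L))
  expect_true(isTRUE(attr(cr, "unconstrained")))
  # random networks: all repertoires sum to 1 within 1e-12
  for (seed in 1:4) {
    net <- random_test_network(seed, n = 3L)
    st <- state_to_bits(seed %% 8L, 3L)
    tp <- condition_tpm(full_tpm(net), 1:3, st)
    for (mech in list(integer(0), 1L, c(1L, 3L), 1:3))
      for (purv in list(1L, c(2L, 3L), 1:3)) {
        expect_equal(sum(cause_repertoire(tp, mech, purv, st)$p), 1,
                     tolerance = 1e-12)
        expect_equal(sum(effect_repertoire(tp, mech, purv, st)$p), 1,
                     tolerance = 1e-12)
      }
  }
})

test_that("hamming EMD is exact and a metric", {
  expect_equal(emd_hamming(c(1, 0), c(0, 1)), 1)
  expect_equal(emd_hamming(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_equal(emd_hamming(c(0.5, 0.5), c(0.5, 0.5)), 0)
  # agreement with the independent LP solver on random distributions
  set.seed(31)
  for (i in 1:8) {
    p <- runif(8); p <- p / sum(p)
    q <- runif(8); q <- q / sum(q)
    expect_equal(emd_hamming(p, q), oracle_emd(p, q, 3L),
                 tolerance = 1e-9)
  }
  # metric properties: symmetry and triangle inequality
  set.seed(32)
  for (i in 1:6) {
    p <- runif(8); p <- p / sum(p)
    q <- runif(8); q <- q / sum(q)
    r <- runif(8); r <- r / sum(r)
    expect_equal(emd_hamming(p, q), emd_hamming(q, p), tolerance = 1e-9)
    expect_lte(emd_hamming(p, r),
               emd_hamming(p, q) + emd_hamming(q, r) + 1e-9)
  }
})

test_that("mechanism phi matches hand-derived fixture values", {
  # single self-copy node, state on: phi = 0.5 on both sides
  net <- logic_network(list(list(inputs = 1L, table = c(0L, 1L))))
  tp <- condition_tpm(full_tpm(net), 1L, 1L)
  cpt <- mechanism_phi(tp, 1L, 1L)
  expect_equal(cpt$phi, 0.5)
  expect_equal(cpt$cause$phi, 0.5)
  expect_equal(cpt$effect$phi, 0.5)
  # a mechanism with no connections specifies no concept
  net0 <- logic_network(list(NULL, list(inputs = 2L, table = c(0L, 1L))))
  tp0 <- condition_tpm(full_tpm(net0), 1:2, c(0L, 0L))
  expect_null(mechanism_phi(tp0, 1L, c(0L, 0L)))
})

test_that("engine equals the naive exhaustive reference on the toy suite", {
  suite <- toy_network_suite()
  expect_gte(length(suite), 4L)
  for (entry in suite) {
    net <- entry$network
    n <- net$n
    bits <- entry$state
    tp <- condition_tpm(full_tpm(net), seq_len(n), bits)
    T <- oracle_sbs(net, seq_len(n), bits)
    # phi of every mechanism
    for (mp in oracle_subsets(seq_len(n), include_empty = FALSE)) {
      cpt_e <- mechanism_phi(tp, mp, bits)
      cpt_o <- oracle_concept(T, n, mp, bits[mp])
      expect_equal(if (is.null(cpt_e)) 0 else cpt_e$phi,
                   if (is.null(cpt_o)) 0 else cpt_o$phi,
                   tolerance = 1e-9,
                   label = sprintf("%s mech {%s} phi", entry$name,
                                   paste(mp, collapse = ",")))
      if (!is.null(cpt_e) && !is.null(cpt_o)) {
        expect_equal(sort(cpt_e$cause$purview), sort(cpt_o$cause_purview))
        expect_equal(sort(cpt_e$effect$purview),
                     sort(cpt_o$effect_purview))
      }
    }
    # concept set (which mechanisms bear phi > 0) and system Phi
    eng <- big_phi(tp, bits)
    ora <- oracle_big_phi(net, seq_len(n), bits)
    expect_equal(eng$phi, ora$phi, tolerance = 1e-9, label = entry$name)
    mechs_e <- sort(vapply(eng$constellation, function(cc)
      paste(cc$mechanism, collapse = ","), character(1)))
    mechs_o <- sort(vapply(ora$constellation, function(cc)
      paste(cc$mechanism_pos, collapse = ","), character(1)))
    expect_equal(mechs_e, mechs_o, label = entry$name)
    # stored reference values from the shipped suite file
    expect_equal(eng$phi, entry$big_phi, tolerance = 1e-9)
    mc <- main_complex(net, bits, use_cache = FALSE)
    expect_equal(mc$phi, entry$main_complex$phi, tolerance = 1e-9)
    if (entry$main_complex$phi > 0)
      expect_equal(sort(mc$nodes), sort(entry$main_complex$nodes))
  }
})

test_that("engine equals the reference on random small networks", {
  for (seed in c(101, 102, 103, 104)) {
    net <- random_test_network(seed)
    n <- net$n
    st <- state_to_bits(seed %% 2^n, n)
    eng <- main_complex(net, st, use_cache = FALSE)
    ora <- oracle_main_complex(net, st, seq_len(n))
    expect_equal(eng$phi, ora$phi, tolerance = 1e-9,
                 label = paste("seed", seed))
    if (eng$phi > 0)
      expect_equal(sort(as.integer(eng$nodes)), sort(ora$nodes),
                   label = paste("seed", seed))
  }
})

test_that("phi values are invariant under node relabeling", {
  net <- logic_network(list(
    list(inputs = c(2L, 3L), table = c(0L, 0L, 0L, 1L)),
    list(inputs = 1L, table = c(0L, 1L)),
    list(inputs = 2L, table = c(0L, 1L))))
  bits <- c(1L, 1L, 1L)
  perm <- c(3L, 1L, 2L) # node i becomes perm[i]
  relabel <- function(net, perm) {
    g2 <- vector("list", net$n)
    for (i in seq_len(net$n)) {
      g <- net$gates[[i]]
      g$inputs <- perm[g$inputs]
      g2[[perm[i]]] <- g
    }
    logic_network(g2)
  }
  net2 <- relabel(net, perm)
  bits2 <- integer(3); bits2[perm] <- bits
  r1 <- main_complex(net, bits, use_cache = FALSE)
  r2 <- main_complex(net2, bits2, use_cache = FALSE)
  expect_equal(r1$phi, r2$phi, tolerance = 1e-9)
  expect_equal(sort(perm[r1$nodes]), sort(r2$nodes))
  phis1 <- sort(vapply(r1$constellation, `[[`, numeric(1), "phi"))
  phis2 <- sort(vapply(r2$constellation, `[[`, numeric(1), "phi"))
  expect_equal(phis1, phis2, tolerance = 1e-9)
})

test_that("unconnected brains carry zero Phi everywhere", {
  b <- empty_brain()
  for (s in c(0L, 1L, 37L, 255L)) {
    res <- main_complex(b, state_to_bits(s, 8L), use_cache = FALSE)
    expect_equal(res$phi, 0)
  }
  recs <- run_trials(b, enumerate_trials("easy")[1:3, ])
  ph <- phi_timeseries(b, recs)
  expect_true(all(ph$phi == 0))
})

test_that("memoized main-complex calls equal fresh ones", {
  b <- random_test_brain(17)
  st <- c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L)
  clear_phi_cache()
  r1 <- main_complex(b, st, use_cache = TRUE)  # fills the cache
  r2 <- main_complex(b, st, use_cache = TRUE)  # cache hit
  r3 <- main_complex(b, st, use_cache = FALSE) # fresh
  expect_equal(r1$phi, r3$phi)
  expect_identical(r1, r2)
  expect_equal(sort(r1$nodes), sort(r3$nodes))
})

test_that("phi time series equals per-state main-complex evaluation", {
  b <- random_test_brain(23)
  recs <- run_trials(b, enumerate_trials("easy")[c(1, 17), ])
  ph <- phi_timeseries(b, recs)
  expect_equal(nrow(ph), 66L)
  # recompute a few rows without the cache
  for (i in c(1L, 20L, 50L)) {
    st <- as.integer(ph[i, c("sL", "sR", "h1", "h2", "h3", "h4",
                             "mL", "mR")])
    expect_equal(ph$phi[i], main_complex(b, st, use_cache = FALSE)$phi)
  }
  # identical states give identical phi
  keys <- apply(ph[, c("sL", "sR", "h1", "h2", "h3", "h4", "mL", "mR")],
                1, paste, collapse = "")
  expect_true(all(tapply(ph$phi, keys, function(x)
    length(unique(x))) == 1L))
})

test_that("TPM files round-trip through CSV and JSON", {
  net <- random_test_network(55, n = 3L)
  tp <- condition_tpm(full_tpm(net), c(1L, 3L), c(0L, 1L, 1L))
  for (ext in c(".csv", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    tpm_write(tp, f)
    tp2 <- tpm_read(f)
    expect_equal(tp2$nodes, tp$nodes)
    expect_equal(unname(as.matrix(tp2$probs)), unname(tp$probs))
    expect_equal(tp2$bg_nodes, tp$bg_nodes)
    expect_equal(tp2$bg_state, tp$bg_state)
  }
})
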