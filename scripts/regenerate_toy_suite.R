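#!/usr/bin/env Rscript
# Regenerates inst/extdata/toy_networks.json from the naive exhaustive
# reference implementation (tests/testthat/helper-oracle.R). Run from the
# repository root with the package installed:
#   Rscript scripts/regenerate_toy_suite.R
suppressPackageStartupMessages(library(animatphi))
source("tests/testthat/helper-oracle.R")

defs <- animatphi:::toy_network_gates()
networks <- lapply(names(defs), function(nm) {
  d <- defs[[nm]]
  net <- logic_network(d$gates)
  n <- net$n
  bits <- as.integer(d$state)
  T <- oracle_sbs(net, 1:n, bits)
  mechs <- list()
  for (mp in oracle_subsets(1:n, include_empty = FALSE)) {
    cpt <- oracle_concept(T, n, mp, bits[mp])
    mechs[[length(mechs) + 1L]] <- list(
      mechanism = paste(mp, collapse = ","),
      phi = if (is.null(cpt)) 0 else cpt$phi)
  }
  bp <- oracle_big_phi(net, 1:n, bits)
  mc <- oracle_main_complex(net, bits, 1:n)
  list(name = nm,
       gates = lapply(net$gates, function(g)
         list(inputs = g$inputs, table = paste(g$table, collapse = ""))),
       state = bits,
       phi_mechanisms = mechs,
       big_phi = bp$phi,
       main_complex = list(nodes = mc$nodes, phi = mc$phi))
})
obj <- list(
  provenance = paste(
    "Generated programmatically by the naive exhaustive reference",
    "implementation (tests/testthat/helper-oracle.R); regenerate with",
    "scripts/regenerate_toy_suite.R. Do not hand-edit."),
  networks = networks)
writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE),
           "inst/extdata/toy_networks.json")
cat("regenerated inst/extdata/toy_networks.json with",
    length(networks), "networks\n")
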