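# Shared brain/network generators for the test suite.

random_test_brain <- function(seed, max_arity = 3L) {
  set.seed(seed)
  markov_brain(lapply(1:6, function(i) {
    k <- sample(0:max_arity, 1L)
    if (k == 0L) return(NULL)
    list(inputs = sample(1:6, k, replace = TRUE),
         table = sample(0:1, 2^k, replace = TRUE))
  }))
}

random_test_network <- function(seed, n = NULL, max_arity = 2L) {
  set.seed(seed)
  n <- n %||% sample(2:3, 1L)
  logic_network(lapply(1:n, function(i) {
    k <- sample(0:max_arity, 1L)
    if (k == 0L) return(NULL)
    list(inputs = sample(1:n, k, replace = TRUE),
         table = sample(0:1, 2^k, replace = TRUE))
  }))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
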