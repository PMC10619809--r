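#' Markov-brain animats
#'
#' An animat's controller is a deterministic logic network of 8 binary
#' nodes: nodes 1--2 are sensors (left, right), 3--6 hidden, 7--8 motors
#' (left, right). Every non-sensor node carries a *gate*: an ordered list
#' of input nodes and a truth table mapping each input combination to 0/1.
#' Sensors have no gates (they are set by the world) and motors cannot be
#' gate inputs (they have no outputs). A gate with no inputs emits the
#' constant stored in its length-1 truth table, so a fully unconnected
#' brain is inert.
#'
#' Truth-table indexing: the first listed input is the least significant
#' bit, so `table[1 + sum(bits * 2^(0:(k-1)))]` is the output.
#'
#' @name markov_brain
NULL

N_NODES <- 8L
SENSOR_NODES <- 1:2
HIDDEN_NODES <- 3:6
MOTOR_NODES <- 7:8
NON_SENSOR_NODES <- 3:8
LEGAL_INPUT_NODES <- 1:6 # sensors + hidden; motors have no outputs

#' Construct a Markov brain
#'
#' @param gates a named or ordered list of 6 gates for nodes 3--8. Each
#'   gate is `list(inputs = <integer vector of node ids in 1:6>,
#'   table = <0/1 vector of length 2^length(inputs)>)`. `NULL` entries
#'   become empty gates (no inputs, constant off).
#' @return a validated `markov_brain` object.
#' @examples
#' # hidden node 3 copies the left sensor:
#' b <- markov_brain(list(list(inputs = 1L, table = c(0L, 1L))))
#' @export
markov_brain <- function(gates = NULL) {
  full <- rep(list(list(inputs = integer(0), table = 0L)), 6L)
  if (!is.null(gates)) {
    stopifnot(is.list(gates), length(gates) <= 6L)
    for (i in seq_along(gates)) if (!is.null(gates[[i]])) full[[i]] <- gates[[i]]
  }
  brain <- structure(list(gates = full), class = "markov_brain")
  validate_brain(brain)
}

#' @rdname markov_brain
#' @param brain object to validate.
#' @export
validate_brain <- function(brain) {
  stopifnot(inherits(brain, "markov_brain"), length(brain$gates) == 6L)
  brain$gates <- lapply(brain$gates, function(g) {
    g$inputs <- as.integer(g$inputs)
    g$table <- as.integer(g$table)
    if (any(g$inputs %in% MOTOR_NODES))
      stop("motor nodes cannot be gate inputs", call. = FALSE)
    if (any(g$inputs < 1L | g$inputs > N_NODES))
      stop("gate input out of range", call. = FALSE)
    if (length(g$table) != 2^length(g$inputs))
      stop("truth table length must be 2^(number of inputs)", call. = FALSE)
    if (!all(g$table %in% c(0L, 1L)))
      stop("truth table entries must be 0/1", call. = FALSE)
    g
  })
  brain
}

#' An unconnected (generation-0) brain
#' @return a `markov_brain` whose non-sensor nodes all have empty gates.
#' @export
empty_brain <- function() markov_brain()

#' Synchronous brain update
#'
#' Computes the next hidden and motor states from the current full network
#' state. All non-sensor nodes update simultaneously; each reads the
#' *current* values of its input nodes and looks up its truth table.
#' Sensor values in the returned state are carried over unchanged (sensors
#' are set by the world, not the network).
#'
#' @param brain a `markov_brain`.
#' @param state integer vector of 8 current node values (0/1), sensors
#'   already set for this timestep.
#' @return integer vector of 8 next node values.
#' @export
update_brain <- function(brain, state) {
  stopifnot(length(state) == N_NODES, all(state %in% c(0L, 1L)))
  nxt <- as.integer(state)
  for (i in 1:6) {
    g <- brain$gates[[i]]
    k <- length(g$inputs)
    idx <- if (k == 0L) 1L
           else 1L + sum(state[g$inputs] * 2L^(0:(k - 1L)))
    nxt[i + 2L] <- g$table[idx]
  }
  nxt
}

#' Mirror a brain's left/right roles
#'
#' Swaps the sensor ids in every gate's input list and exchanges the two
#' motor gates, producing the lateral mirror image of the controller.
#' Together with a mirrored trial this yields the mirrored trial record.
#'
#' @param brain a `markov_brain`.
#' @return the mirrored `markov_brain`.
#' @export
mirror_brain <- function(brain) {
  swap <- function(v) { v[v == 1L] <- 99L; v[v == 2L] <- 1L; v[v == 99L] <- 2L; v }
  g <- lapply(brain$gates, function(gt) { gt$inputs <- swap(gt$inputs); gt })
  g[5:6] <- g[6:5] # motor gates (nodes 7, 8)
  markov_brain(g)
}

# Canonical string key for memoization / fitness caching.
brain_key <- function(brain) {
  paste(vapply(brain$gates, function(g) {
    paste0("i", paste(g$inputs, collapse = ","), "t",
           paste(g$table, collapse = ""))
  }, character(1)), collapse = "|")
}

#' Serialize a brain to JSON
#'
#' Round-trip lossless encoding of node roles, per-gate input lists and
#' truth tables (as bit strings).
#'
#' @param brain a `markov_brain`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
brain_to_json <- function(brain, path = NULL) {
  obj <- list(
    nodes = list(sensors = SENSOR_NODES, hidden = HIDDEN_NODES,
                 motors = MOTOR_NODES),
    gates = lapply(seq_along(brain$gates), function(i) {
      g <- brain$gates[[i]]
      list(node = i + 2L, inputs = g$inputs,
           table = paste(g$table, collapse = ""))
    })
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname brain_to_json
#' @param json JSON string or file path produced by [brain_to_json()].
#' @export
brain_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  gates <- lapply(obj$gates, function(g) {
    list(inputs = as.integer(unlist(g$inputs)),
         table = as.integer(strsplit(g$table, "")[[1]]))
  })
  markov_brain(gates)
}
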