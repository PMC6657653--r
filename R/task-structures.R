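#' Task state structures and transition matrices
#'
#' A `state_spec` describes the state set of a two-sequence task design:
#' eight decodable states forming two disjoint chains of four
#' (`A -> B -> C -> D` and `A' -> B' -> C' -> D'`), the binary transition
#' matrix of the *rule-defined* (true, unscrambled) order, and the binary
#' transition matrix of the *visual* (scrambled presentation) order. Each
#' state also carries two factor labels: its ordinal position within its
#' chain (1..4) and which of the two sequences it belongs to.
#'
#' Two designs are supported. In `"study1"` the presentation stream is built
#' from pair stages (`[CD, C'D'] [AB, A'B'] [BC, B'C']`), so every directed
#' pair of the rule order also occurs visually, but never chained beyond
#' length 2. In `"study2"` the presentation order is a per-seed random
#' permutation of the eight states in two stages of four, constrained so
#' that consecutive stimuli alternate between the two sequences; as a
#' consequence the visual order shares no directed pair with the rule order.
#'
#' @name task_structures
NULL

#' Create a binary transition matrix from directed edges
#'
#' @param n_states number of states.
#' @param edges two-column integer matrix of directed edges (from, to).
#' @param labels optional state labels for dimnames.
#' @return An `n_states x n_states` binary matrix with entry `(i, j) = 1`
#'   iff state `j` directly follows state `i`.
#' @export
transition_matrix <- function(n_states, edges, labels = NULL) {
  stopifnot(is.matrix(edges) || is.data.frame(edges))
  edges <- as.matrix(edges)
  stopifnot(ncol(edges) == 2L, all(edges >= 1), all(edges <= n_states))
  P <- matrix(0, n_states, n_states)
  P[edges] <- 1
  if (any(diag(P) != 0)) stop("transition matrix must have a zero diagonal")
  if (!is.null(labels)) dimnames(P) <- list(labels, labels)
  P
}

edges_of <- function(P) {
  idx <- which(P != 0, arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

# Directed edges of consecutive elements of a presentation stream, optionally
# split into stages (no edge across a stage boundary).
stream_edges <- function(stream, stage_sizes) {
  stops <- cumsum(stage_sizes)
  keep <- setdiff(seq_len(length(stream) - 1L), stops)
  cbind(from = stream[keep], to = stream[keep + 1L])
}

#' Construct the state structure of a task design
#'
#' @param design `"study1"` or `"study2"`.
#' @param seed integer seed; used by `"study2"` to draw the randomized
#'   admissible presentation order (rejection sampling over permutations
#'   under the sequence-alternation constraint, uniform over the admissible
#'   set). Ignored for `"study1"`, whose scrambling is fixed.
#' @return A `state_spec` list: `n_states`, `labels`, `rule_order`,
#'   `visual_order` (binary transition matrices), `position_of`,
#'   `sequence_of` (integer vectors), `presentation` (the visual stream as
#'   state indices) and `design`.
#' @export
make_study_structure <- function(design = c("study1", "study2"), seed = 1L) {
  design <- match.arg(design)
  labels <- c("A", "B", "C", "D", "A'", "B'", "C'", "D'")
  n <- 8L
  chains <- list(1:4, 5:8)
  rule_edges <- do.call(rbind, lapply(chains, function(ch)
    cbind(from = ch[-4L], to = ch[-1L])))
  rule_order <- transition_matrix(n, rule_edges, labels)
  position_of <- c(1:4, 1:4)
  sequence_of <- rep(1:2, each = 4L)

  if (design == "study1") {
    # Pair stages [CD, C'D'], [AB, A'B'], [BC, B'C']; consecutive stimuli
    # within a stage form the visually experienced transitions.
    stages <- list(c(3L, 4L, 7L, 8L), c(1L, 2L, 5L, 6L), c(2L, 3L, 6L, 7L))
    stream <- unlist(stages)
    vis_edges <- stream_edges(stream, rep(4L, 3L))
  } else {
    stream <- with_seed(seed, {
      repeat {
        cand <- sample.int(n)
        seqs <- sequence_of[cand]
        ok1 <- all(diff(seqs[1:4]) != 0)    # alternation within stage 1
        ok2 <- all(diff(seqs[5:8]) != 0)    # alternation within stage 2
        if (ok1 && ok2) break
      }
      cand
    })
    vis_edges <- stream_edges(stream, c(4L, 4L))
  }
  visual_order <- transition_matrix(n, vis_edges, labels)

  spec <- structure(list(
    n_states = n, labels = labels, design = design,
    rule_order = rule_order, visual_order = visual_order,
    position_of = position_of, sequence_of = sequence_of,
    presentation = stream, seed = if (design == "study2") as.integer(seed) else NA_integer_
  ), class = "state_spec")
  validate_state_spec(spec)
  spec
}

#' Validate the structural invariants of a `state_spec`
#'
#' Checks the two-chain rule structure, and the design-specific constraints
#' on the visual order (shared pairs for study 1; zero shared pairs and
#' sequence alternation for study 2).
#'
#' @param spec a `state_spec`.
#' @return `spec` invisibly; errors on violation.
#' @export
validate_state_spec <- function(spec) {
  stopifnot(inherits(spec, "state_spec"))
  P <- spec$rule_order
  if (!all(P %in% c(0, 1)) || any(diag(P) != 0))
    stop("rule_order must be binary with zero diagonal")
  outd <- rowSums(P)
  ind <- colSums(P)
  if (!all(outd <= 1) || !all(ind <= 1))
    stop("rule_order must be a union of chains (in/out degree <= 1)")
  if (sum(P) != 6) stop("rule_order of the 8-state design must have 6 edges")
  re <- edges_of(spec$rule_order)
  ve <- edges_of(spec$visual_order)
  shared <- sum(paste(re[, 1], re[, 2]) %in% paste(ve[, 1], ve[, 2]))
  if (spec$design == "study2") {
    if (shared != 0)
      stop("study2 visual order must share no directed pair with the rule order")
    seqs <- spec$sequence_of[spec$presentation]
    if (any(diff(seqs[1:4]) == 0) || any(diff(seqs[5:8]) == 0))
      stop("study2 presentation must alternate between the two sequences")
  } else {
    if (shared != 6)
      stop("study1 visual order must contain every directed rule pair")
  }
  invisible(spec)
}

#' @export
print.state_spec <- function(x, ...) {
  cat(sprintf("state_spec (%s): %d states %s\n", x$design, x$n_states,
              paste(x$labels, collapse = " ")))
  cat(" rule edges:  ",
      paste(apply(edges_of(x$rule_order), 1L, function(e)
        paste0(x$labels[e[1]], ">", x$labels[e[2]])), collapse = " "), "\n")
  cat(" visual edges:",
      paste(apply(edges_of(x$visual_order), 1L, function(e)
        paste0(x$labels[e[1]], ">", x$labels[e[2]])), collapse = " "), "\n")
  invisible(x)
}

#' Factor (position / sequence) groupings of a state structure
#'
#' @param spec a `state_spec`.
#' @return A `factor_map` list with `position_groups` (position index ->
#'   states at that ordinal position, one per sequence) and
#'   `sequence_groups` (sequence index -> its four states).
#' @export
factor_labels <- function(spec) {
  stopifnot(inherits(spec, "state_spec"))
  structure(list(
    position_groups = lapply(1:4, function(p) which(spec$position_of == p)),
    sequence_groups = lapply(1:2, function(s) which(spec$sequence_of == s))
  ), class = "factor_map")
}

#' Transition matrix of the position code
#'
#' The single four-state chain `position 1 -> 2 -> 3 -> 4` used when the
#' sequenceness machinery is applied to decoded position codes (e.g., for
#' transfer replay before stimulus exposure).
#'
#' @return a 4 x 4 binary transition matrix.
#' @export
position_chain <- function() {
  transition_matrix(4L, cbind(1:3, 2:4), paste0("pos", 1:4))
}

#' Serialize / restore a `state_spec` as JSON
#'
#' @param spec a `state_spec`.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @return `state_spec_to_json`: the path (or JSON string).
#'   `state_spec_from_json`: the restored `state_spec`.
#' @export
state_spec_to_json <- function(spec, path = NULL) {
  doc <- list(
    design = spec$design, n_states = spec$n_states, labels = spec$labels,
    rule_edges = edges_of(spec$rule_order),
    visual_edges = edges_of(spec$visual_order),
    position_of = spec$position_of, sequence_of = spec$sequence_of,
    presentation = spec$presentation
  )
  if (!is.na(spec$seed)) doc$seed <- spec$seed
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname state_spec_to_json
#' @param json a path to, or the string of, a JSON document produced by
#'   [state_spec_to_json()].
#' @export
state_spec_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  spec <- structure(list(
    n_states = as.integer(doc$n_states), labels = doc$labels,
    design = doc$design,
    rule_order = transition_matrix(doc$n_states, as.matrix(doc$rule_edges), doc$labels),
    visual_order = transition_matrix(doc$n_states, as.matrix(doc$visual_edges), doc$labels),
    position_of = as.integer(doc$position_of),
    sequence_of = as.integer(doc$sequence_of),
    presentation = as.integer(doc$presentation),
    seed = if (is.null(doc$seed) || is.na(doc$seed)) NA_integer_ else as.integer(doc$seed)
  ), class = "state_spec")
  validate_state_spec(spec)
  spec
}
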