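#' Population specification for a breeding design
#'
#' Describes one source population's contribution to a breeding design:
#' either a number of unique-pair full-sib matings (experiment 1 style) or a
#' number of complete 2x2 diallel matrices, optionally with extra irregular
#' crosses (experiment 2 style).
#'
#' @param name Population label, unique within an experiment.
#' @param n_pairs Number of unique sire-dam pairs (full-sib design). Each
#'   parent is used in exactly one cross.
#' @param n_matrices Number of complete 2x2 diallel matrices (two dams each
#'   crossed with the same two sires, i.e. 4 crosses per matrix).
#' @param n_extra_crosses Extra irregular crosses appended after the complete
#'   matrices. They are generated as maternal half-sib pairs: each pair of
#'   extra crosses shares one dam mated to two unique sires (an odd final
#'   cross gets its own dam and sire).
#' @param origin Either \code{"wild"} or \code{"hatchery"}; metadata only.
#' @return An object of class \code{pop_spec}.
#' @examples
#' pop_spec("Avaan", n_pairs = 11)
#' pop_spec("Kavlingean", n_matrices = 4, n_extra_crosses = 2)
#' @export
pop_spec <- function(name, n_pairs = NULL, n_matrices = NULL,
                     n_extra_crosses = 0L, origin = c("wild", "hatchery")) {
  origin <- match.arg(origin)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string")
  if (is.null(n_pairs) == is.null(n_matrices))
    stop("give exactly one of 'n_pairs' or 'n_matrices'")
  for (v in list(n_pairs, n_matrices, n_extra_crosses)) {
    if (!is.null(v) && (length(v) != 1L || is.na(v) || v < 0 || v != round(v)))
      stop("counts must be single non-negative integers")
  }
  structure(
    list(name = name,
         n_pairs = if (!is.null(n_pairs)) as.integer(n_pairs),
         n_matrices = if (!is.null(n_matrices)) as.integer(n_matrices),
         n_extra_crosses = as.integer(n_extra_crosses),
         origin = origin),
    class = "pop_spec")
}

#' Build a breeding design from population specifications
#'
#' Experiment-1 designs mate each dam with a unique sire from the same
#' population (one cross per parent). Experiment-2 designs build complete
#' 2x2 diallel matrices (each sire and each dam in exactly two crosses)
#' plus any irregular extra crosses declared in the spec.
#'
#' Labels are deterministic: sires \code{"<POP>-S01"}, dams \code{"<POP>-D01"},
#' crosses \code{"<POP>-X01"}. The \code{seed} is recorded for provenance and
#' reserved for future stochastic layout choices; the current label scheme is
#' fully deterministic.
#'
#' @param specs A list of \code{\link{pop_spec}} objects (a single spec is
#'   accepted).
#' @param experiment 1 (unique pairs) or 2 (incomplete diallel).
#' @param seed Integer recorded in the design.
#' @return An object of class \code{breeding_design}: list with
#'   \code{experiment}, \code{populations} (data frame) and \code{crosses}
#'   (data frame with \code{cross_id}, \code{sire_id}, \code{dam_id},
#'   \code{population}).
#' @examples
#' d <- build_design(list(pop_spec("A", n_pairs = 3)), experiment = 1)
#' nrow(d$crosses)
#' @export
build_design <- function(specs, experiment, seed = 1L) {
  if (inherits(specs, "pop_spec")) specs <- list(specs)
  if (!length(specs) || !all(vapply(specs, inherits, TRUE, "pop_spec")))
    stop("'specs' must be a list of pop_spec objects")
  if (!experiment %in% c(1L, 2L)) stop("'experiment' must be 1 or 2")
  nms <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate population names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  crosses <- lapply(specs, function(sp) {
    if (experiment == 1L) {
      if (is.null(sp$n_pairs))
        stop("experiment 1 requires 'n_pairs' for population ", sp$name)
      n <- sp$n_pairs
      if (n == 0L) return(NULL)
      data.frame(
        cross_id = sprintf("%s-X%02d", sp$name, seq_len(n)),
        sire_id = sprintf("%s-S%02d", sp$name, seq_len(n)),
        dam_id = sprintf("%s-D%02d", sp$name, seq_len(n)),
        population = sp$name, stringsAsFactors = FALSE)
    } else {
      if (is.null(sp$n_matrices))
        stop("experiment 2 requires 'n_matrices' for population ", sp$name)
      out <- NULL
      k <- 0L  # running cross index
      for (m in seq_len(sp$n_matrices)) {
        sires <- sprintf("%s-S%02d", sp$name, 2L * m - 1:0)[c(1, 2)]
        dams <- sprintf("%s-D%02d", sp$name, 2L * m - 1:0)[c(1, 2)]
        grid <- expand.grid(s = sires, d = dams, stringsAsFactors = FALSE)
        out <- rbind(out, data.frame(
          cross_id = sprintf("%s-X%02d", sp$name, k + seq_len(4L)),
          sire_id = grid$s, dam_id = grid$d,
          population = sp$name, stringsAsFactors = FALSE))
        k <- k + 4L
      }
      if (sp$n_extra_crosses > 0L) {
        ns <- sp$n_matrices * 2L
        nd <- sp$n_matrices * 2L
        # maternal half-sib pairs: one shared dam, two unique sires per pair
        for (i in seq_len(sp$n_extra_crosses)) {
          dam <- sprintf("%s-D%02d", sp$name, nd + ceiling(i / 2))
          sire <- sprintf("%s-S%02d", sp$name, ns + i)
          out <- rbind(out, data.frame(
            cross_id = sprintf("%s-X%02d", sp$name, k + i),
            sire_id = sire, dam_id = dam,
            population = sp$name, stringsAsFactors = FALSE))
        }
      }
      out
    }
  })
  crosses <- do.call(rbind, crosses)
  if (is.null(crosses))
    crosses <- data.frame(cross_id = character(), sire_id = character(),
                          dam_id = character(), population = character(),
                          stringsAsFactors = FALSE)
  pops <- data.frame(
    name = nms,
    origin = vapply(specs, `[[`, "", "origin"),
    n_crosses = vapply(nms, function(p) sum(crosses$population == p), 0L),
    stringsAsFactors = FALSE)
  structure(list(experiment = as.integer(experiment), populations = pops,
                 crosses = crosses, seed = as.integer(seed)),
            class = "breeding_design")
}

#' @export
print.breeding_design <- function(x, ...) {
  cat(sprintf("breeding_design (experiment %d): %d populations, %d crosses\n",
              x$experiment, nrow(x$populations), nrow(x$crosses)))
  print(x$populations, row.names = FALSE)
  invisible(x)
}

#' Build a stocking plan from a design and an egg allocation rule
#'
#' @param design A \code{\link{breeding_design}}.
#' @param allocation Named list, one element per stream. Each element is
#'   either a single number (eggs per cross, applied to all non-excluded
#'   crosses) or a named numeric vector giving eggs for an explicit subset of
#'   crosses.
#' @param exclude Optional named list mapping a stream to cross ids to leave
#'   out of that stream (used for families with too few eggs).
#' @return An object of class \code{stocking_plan}: a data frame
#'   (\code{cross_id}, \code{stream}, \code{n_eggs}) with attribute
#'   \code{"design"}.
#' @examples
#' d <- build_design(list(pop_spec("A", n_pairs = 2)), experiment = 1)
#' build_stocking(d, list(experimental = 200))
#' @export
build_stocking <- function(design, allocation, exclude = NULL) {
  stopifnot(inherits(design, "breeding_design"))
  if (!is.list(allocation) || is.null(names(allocation)) ||
      any(!nzchar(names(allocation))))
    stop("'allocation' must be a named list keyed by stream")
  known <- design$crosses$cross_id
  if (!is.null(exclude)) {
    bad <- setdiff(names(exclude), names(allocation))
    if (length(bad)) stop("exclusion for unknown stream: ",
                          paste(bad, collapse = ", "))
    badx <- setdiff(unlist(exclude), known)
    if (length(badx)) stop("exclusion references unknown cross: ",
                           paste(badx, collapse = ", "))
  }
  entries <- lapply(names(allocation), function(stream) {
    rule <- allocation[[stream]]
    if (!is.numeric(rule) || any(rule < 0))
      stop("allocation for stream ", stream, " must be non-negative numeric")
    if (is.null(names(rule))) {
      if (length(rule) != 1L)
        stop("unnamed allocation for stream ", stream, " must be a scalar")
      ids <- setdiff(known, exclude[[stream]])
      if (!length(ids)) return(NULL)
      data.frame(cross_id = ids, stream = stream,
                 n_eggs = as.integer(rule), stringsAsFactors = FALSE)
    } else {
      badx <- setdiff(names(rule), known)
      if (length(badx)) stop("allocation references unknown cross: ",
                             paste(badx, collapse = ", "))
      ids <- setdiff(names(rule), exclude[[stream]])
      if (!length(ids)) return(NULL)
      data.frame(cross_id = ids, stream = stream,
                 n_eggs = as.integer(rule[ids]), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, entries)
  if (is.null(out))
    out <- data.frame(cross_id = character(), stream = character(),
                      n_eggs = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, design = design, class = c("stocking_plan", "data.frame"))
}

#' Total eggs stocked, overall or by stream
#' @param plan A \code{\link{build_stocking}} plan.
#' @param by_stream If \code{TRUE}, return a named vector per stream.
#' @export
stocking_total <- function(plan, by_stream = FALSE) {
  stopifnot(inherits(plan, "stocking_plan"))
  if (by_stream) tapply(plan$n_eggs, plan$stream, sum) else sum(plan$n_eggs)
}

#' The two published brown-trout breeding designs
#'
#' Convenience constructors for the study designs analysed throughout the
#' package documentation: experiment 1 (2003) used unique-pair matings in
#' five populations (12 + 12 + 12 + 11 + 10 pairs, 57 full-sib families,
#' 200 eggs per family in the experimental stream); experiment 2 (2004) used
#' an incomplete 2x2 diallel in four populations (six matrices each, except
#' one population with four matrices plus two maternal half-sib crosses,
#' 90 crosses, 100 eggs per cross in the experimental stream).
#'
#' @param experiment 1 or 2.
#' @param seed Passed to \code{\link{build_design}}.
#' @return A \code{breeding_design}.
#' @export
study_design <- function(experiment, seed = 1L) {
  if (experiment == 1L) {
    build_design(list(
      pop_spec("Dalalven2", n_pairs = 12, origin = "hatchery"),
      pop_spec("Dalalven8", n_pairs = 12, origin = "hatchery"),
      pop_spec("Norumsan", n_pairs = 12, origin = "wild"),
      pop_spec("Avaan", n_pairs = 11, origin = "hatchery"),
      pop_spec("Jorlandaan", n_pairs = 10, origin = "wild")),
      experiment = 1L, seed = seed)
  } else if (experiment == 2L) {
    build_design(list(
      pop_spec("Dalalven8", n_matrices = 6, origin = "hatchery"),
      pop_spec("Avaan", n_matrices = 6, origin = "hatchery"),
      pop_spec("Jorlandaan", n_matrices = 6, origin = "wild"),
      pop_spec("Kavlingean", n_matrices = 4, n_extra_crosses = 2,
               origin = "wild")),
      experiment = 2L, seed = seed)
  } else stop("'experiment' must be 1 or 2")
}

#' Streams used in each study year
#' @param experiment 1 or 2.
#' @return Character vector; the first element is the semi-natural
#'   experimental stream, the rest are natural streams.
#' @export
study_streams <- function(experiment) {
  if (experiment == 1L) c("experimental", "Molnboan", "Brattasbacken")
  else c("experimental", "Molnboan", "Brattasbacken", "Sularpsbacken")
}
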