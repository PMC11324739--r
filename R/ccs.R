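#' Build a CCS model from a discretized exam
#'
#' Each slice of one patient's exam in one imaging plane becomes a process
#' `Pi` offering, as alternative summands, every ordering (interleaving) of
#' that slice's discretized feature actions, each ordering ending in the next
#' slice's process; the process after the last slice is `nil`. Because all
#' orderings are included, the order in which features appear is semantically
#' irrelevant.
#'
#' @param tbl A discretized feature table (level labels, see
#'   [discretize_features()]) containing exactly one patient and one plane,
#'   with at least one feature column.
#' @return An object of class `acdx_ccs` with one action per feature per
#'   slice, e.g. `H_variance`.
#' @examples
#' tbl <- tibble::tibble(patient_id = "p1", plane = "coronal",
#'                       slice_index = 1:2,
#'                       FIRST_Variance = c("H", "L"),
#'                       FIRST_Energy = c("L", "M"))
#' build_ccs_model(tbl)
#' @export
build_ccs_model <- function(tbl) {
  if (nrow(tbl) == 0) stop("empty exam", call. = FALSE)
  if (length(unique(tbl$patient_id)) != 1 || length(unique(tbl$plane)) != 1)
    stop("exam must contain exactly one patient and one plane", call. = FALSE)
  feat <- setdiff(names(tbl), .acdx_meta_cols)
  if (length(feat) == 0) stop("exam has no feature columns", call. = FALSE)
  lv <- as.matrix(tbl[feat])
  if (!all(lv %in% c("L", "M", "H")))
    stop("exam is not discretized to L/M/H levels", call. = FALSE)
  tbl <- tbl[order(tbl$slice_index), ]
  slices <- lapply(seq_len(nrow(tbl)), function(i) {
    action_label(unlist(tbl[i, feat], use.names = FALSE), feat)
  })
  new_ccs(slices, patient_id = tbl$patient_id[1], plane = tbl$plane[1],
          features = feat)
}

new_ccs <- function(slices, patient_id = NA_character_, plane = NA_character_,
                    features = NULL) {
  stopifnot(length(slices) >= 1)
  for (s in slices) {
    if (length(s) == 0) stop("slice with no actions", call. = FALSE)
    if (anyDuplicated(s))
      stop("action labels within a slice must be distinct", call. = FALSE)
  }
  structure(
    list(slices = slices, patient_id = patient_id, plane = plane,
         features = features),
    class = "acdx_ccs"
  )
}

#' @export
print.acdx_ccs <- function(x, ...) {
  n <- length(x$slices)
  cat(sprintf("<acdx_ccs> %s (%s): %d slices, %d actions/slice, %d processes (P%d = nil)\n",
              x$patient_id, x$plane, n, length(x$slices[[1]]), n + 1, n + 1))
  invisible(x)
}

# all permutations of seq_len(k), in lexicographic order, as a list
permutations_lex <- function(k) {
  if (k == 1) return(list(1L))
  sub <- permutations_lex(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    for (p in sub) {
      out[[idx]] <- c(first, rest[p])
      idx <- idx + 1L
    }
  }
  out
}

#' Serialize a CCS model to its textual dialect
#'
#' One `proc Pi=...` line per process; the prefix operator is `.`, choice is
#' `+`, and the final process is `nil`. Summands are the full set of k!
#' permutation chains of the slice's actions, emitted in lexicographic order
#' of the (sorted) action labels. With more than 6 actions per slice the
#' factorial expansion is refused unless `allow_huge = TRUE`.
#'
#' @param model An `acdx_ccs`.
#' @param allow_huge Permit serialization beyond 6 actions per slice.
#' @return A single string (lines separated by newlines).
#' @examples
#' m <- new_ccs_from_levels(list(c("H_variance")))
#' cat(serialize_ccs(m))
#' @export
serialize_ccs <- function(model, allow_huge = FALSE) {
  stopifnot(inherits(model, "acdx_ccs"))
  k_max <- max(lengths(model$slices))
  if (k_max > 6 && !allow_huge)
    stop("slice with ", k_max, " actions would expand to ", factorial(k_max),
         " summands; set allow_huge = TRUE to serialize anyway", call. = FALSE)
  n <- length(model$slices)
  lines <- character(n + 1)
  for (i in seq_len(n)) {
    acts <- sort(model$slices[[i]])
    perms <- permutations_lex(length(acts))
    summands <- vapply(perms, function(p) {
      paste(c(acts[p], paste0("P", i + 1)), collapse = ".")
    }, "")
    lines[i] <- paste0("proc P", i, "=", paste(summands, collapse = "+"))
  }
  lines[n + 1] <- paste0("proc P", n + 1, "=nil")
  paste(lines, collapse = "\n")
}

#' Construct a CCS model directly from per-slice action labels
#'
#' @param slices List of character vectors of action labels, one per slice.
#' @param patient_id,plane Optional metadata.
#' @return An `acdx_ccs`.
#' @export
new_ccs_from_levels <- function(slices, patient_id = NA_character_,
                                plane = NA_character_) {
  new_ccs(slices, patient_id, plane)
}

#' Parse the textual CCS dialect
#'
#' Accepts the fragment used for patient models: `proc` definitions, action
#' prefix `.`, choice `+`, process constants and `nil`. Whitespace is
#' ignored; action labels are case-sensitive and must carry an `H_`/`M_`/`L_`
#' prefix. The definitions must form a single linear chain of processes
#' ending in `nil`. If a process's summands are not the complete permutation
#' set of its action multiset, a "partial interleaving" warning is raised and
#' the action set of the first summand is used.
#'
#' @param text The model text (single string or character vector of lines),
#'   or a file path to a `.ccs` file.
#' @return An `acdx_ccs`.
#' @export
parse_ccs <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defs <- list()
  for (ln in seq_along(lines)) {
    l <- gsub("[[:space:]]+", "", lines[ln])
    m <- regmatches(l, regexec("^proc([A-Za-z][A-Za-z0-9]*)=(.+)$", l))[[1]]
    if (length(m) == 0)
      stop("line ", ln, ": not a `proc NAME=body` definition", call. = FALSE)
    name <- m[2]; body <- m[3]
    if (body == "nil") {
      defs[[name]] <- list(nil = TRUE, line = ln)
      next
    }
    summands <- strsplit(body, "+", fixed = TRUE)[[1]]
    parsed <- lapply(summands, function(s) {
      toks <- strsplit(s, ".", fixed = TRUE)[[1]]
      toks <- toks[nzchar(toks)]
      if (length(toks) < 2)
        stop("line ", ln, ": summand `", s,
             "` must be a chain of actions ending in a process", call. = FALSE)
      acts <- toks[-length(toks)]
      bad <- acts[!grepl("^[HML]_[A-Za-z0-9]+$", acts)]
      if (length(bad) > 0)
        stop("line ", ln, ": malformed action label `", bad[1],
             "` (needs H_/M_/L_ prefix)", call. = FALSE)
      list(actions = acts, next_proc = toks[length(toks)])
    })
    defs[[name]] <- list(nil = FALSE, summands = parsed, line = ln)
  }
  if (length(defs) == 0) stop("no process definitions", call. = FALSE)
  # every referenced process must be defined
  for (name in names(defs)) {
    d <- defs[[name]]
    if (d$nil) next
    for (s in d$summands) {
      if (!s$next_proc %in% c(names(defs), "nil"))
        stop("line ", d$line, ": unknown process reference `", s$next_proc,
             "`", call. = FALSE)
    }
  }
  # walk the chain from the first-defined process
  start <- names(defs)[1]
  slices <- list()
  cur <- start
  seen <- character()
  repeat {
    if (cur %in% seen)
      stop("cyclic process references involving `", cur, "`", call. = FALSE)
    seen <- c(seen, cur)
    d <- defs[[cur]]
    if (d$nil) break
    ref <- unique(vapply(d$summands, `[[`, "", "next_proc"))
    if (length(ref) != 1)
      stop("line ", d$line, ": summands of `", cur,
           "` continue into different processes", call. = FALSE)
    sets <- lapply(d$summands, function(s) sort(s$actions))
    same <- all(vapply(sets, identical, TRUE, sets[[1]]))
    acts <- unique(d$summands[[1]]$actions)
    full <- same && length(acts) == length(d$summands[[1]]$actions) &&
      length(d$summands) == factorial(length(acts))
    if (!full)
      warning("process `", cur, "`: partial interleaving (summands are not ",
              "the full permutation set of its actions)", call. = FALSE)
    slices[[length(slices) + 1]] <- acts
    if (ref == "nil") break
    cur <- ref
  }
  new_ccs(slices)
}

#' Expand a CCS model into its labeled transition system
#'
#' States are pairs (slice index, set of that slice's actions already done),
#' plus one final state; state (i, S) offers every remaining action `a` of
#' slice i, moving to (i, S + a), or to the next slice's entry state (or the
#' final state) when `a` completes the slice. This subset construction is
#' strongly bisimilar to the naive expansion of the k! permutation summands,
#' since the actions of a slice commute; for a model with n slices of k
#' actions each it has exactly n (2^k - 1) + 1 states.
#'
#' @param model An `acdx_ccs`.
#' @return An object of class `acdx_lts`: a list with `states` (tibble: `id`,
#'   `slice`, `done` bitmask; the final state has slice `NA`), `transitions`
#'   (tibble: `from`, `label`, `to`), `initial`, `final`, `alphabet`, and
#'   `entry` (ids of slice-entry states, in slice order).
#' @examples
#' m <- new_ccs_from_levels(list(c("H_variance", "L_energy")))
#' lts_from_model(m)
#' @export
lts_from_model <- function(model) {
  stopifnot(inherits(model, "acdx_ccs"))
  n <- length(model$slices)
  k <- lengths(model$slices)
  n_states_slice <- 2L^k - 1L          # all proper subsets incl. empty
  offset <- cumsum(c(0L, n_states_slice))[seq_len(n)]
  final <- sum(n_states_slice) + 1L
  st_id <- integer(); st_slice <- integer(); st_done <- integer()
  fr <- integer(); lab <- character(); to <- integer()
  for (i in seq_len(n)) {
    acts <- model$slices[[i]]
    ki <- k[i]
    full <- bitwShiftL(1L, ki) - 1L
    for (mask in 0:(full - 1L)) {
      sid <- offset[i] + mask + 1L
      st_id <- c(st_id, sid); st_slice <- c(st_slice, i)
      st_done <- c(st_done, mask)
      for (a in seq_len(ki)) {
        bit <- bitwShiftL(1L, a - 1L)
        if (bitwAnd(mask, bit) != 0L) next
        nxt <- bitwOr(mask, bit)
        dest <- if (nxt == full) {
          if (i == n) final else offset[i + 1L] + 1L
        } else offset[i] + nxt + 1L
        fr <- c(fr, sid); lab <- c(lab, acts[a]); to <- c(to, dest)
      }
    }
  }
  states <- tibble::tibble(
    id = c(st_id, final),
    slice = c(st_slice, NA_integer_),
    done = c(st_done, NA_integer_)
  )
  structure(
    list(
      states = states,
      transitions = tibble::tibble(from = fr, label = lab, to = to),
      initial = 1L,
      final = final,
      alphabet = sort(unique(lab)),
      entry = offset + 1L,
      slices = model$slices
    ),
    class = "acdx_lts"
  )
}

#' @export
print.acdx_lts <- function(x, ...) {
  cat(sprintf("<acdx_lts> %d states, %d transitions, alphabet of %d actions\n",
              nrow(x$states), nrow(x$transitions), length(x$alphabet)))
  invisible(x)
}

#' @describeIn lts_from_model `tidy()` returns the transition table.
#' @param x An `acdx_lts`.
#' @param ... Unused.
#' @method tidy acdx_lts
#' @export
tidy.acdx_lts <- function(x, ...) x$transitions
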