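# Independent oracles the implementation is tested against. These are
# deliberately naive: double loops, explicit tree expansion, recursive
# path semantics. They must stay independent of the package's internals.

# brute-force co-occurrence counting: loop over every pixel pair
glcm_oracle <- function(levels, offset, n_levels, symmetric = TRUE,
                        normalize = TRUE) {
  p <- matrix(0, n_levels, n_levels)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in 1:nr) for (c in 1:nc) {
    r2 <- r + offset[1]; c2 <- c + offset[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    a <- levels[r, c]; b <- levels[r2, c2]
    if (is.na(a) || is.na(b)) next
    p[a, b] <- p[a, b] + 1
  }
  if (symmetric) p <- p + t(p)
  if (normalize && sum(p) > 0) p <- p / sum(p)
  p
}

# naive CCS expansion: each slice's k! permutation summands become a tree of
# prefix states; process constants (slice entries, nil) are shared states
naive_lts <- function(slices) {
  n <- length(slices)
  env <- new.env()
  env$id <- 0L
  env$from <- integer(); env$lab <- character(); env$to <- integer()
  new_state <- function() { env$id <- env$id + 1L; env$id }
  entry <- vapply(seq_len(n), function(i) new_state(), 0L)
  final <- new_state()
  expand <- function(i, remaining, sid) {
    for (a in remaining) {
      rest <- setdiff(remaining, a)
      dest <- if (length(rest) == 0) {
        if (i == n) final else entry[i + 1L]
      } else new_state()
      env$from <- c(env$from, sid); env$lab <- c(env$lab, a)
      env$to <- c(env$to, dest)
      if (length(rest) > 0) expand(i, rest, dest)
    }
  }
  for (i in seq_len(n)) expand(i, slices[[i]], entry[i])
  structure(
    list(
      states = tibble::tibble(id = seq_len(env$id)),
      transitions = tibble::tibble(from = env$from, label = env$lab,
                                   to = env$to),
      initial = entry[1],
      final = final,
      alphabet = sort(unique(env$lab))
    ),
    class = "acdx_lts"
  )
}

# strong bisimilarity of two deterministic (per state, at most one successor
# per label) transition systems, by a memoized product walk
bisimilar <- function(l1, l2) {
  succ <- function(l, s) {
    tr <- l$transitions[l$transitions$from == s, ]
    stats::setNames(tr$to, tr$label)
  }
  memo <- new.env()
  walk <- function(s, t) {
    key <- paste(s, t)
    if (!is.null(memo[[key]])) return(memo[[key]])
    memo[[key]] <- TRUE # coinductive hypothesis (harmless: both acyclic)
    a <- succ(l1, s); b <- succ(l2, t)
    if (!setequal(names(a), names(b))) return(memo[[key]] <- FALSE)
    for (lab in names(a)) {
      if (anyDuplicated(names(a)) || anyDuplicated(names(b)))
        stop("bisimilar() assumes deterministic systems")
      if (!walk(a[[lab]], b[[lab]])) return(memo[[key]] <- FALSE)
    }
    memo[[key]] <- TRUE
  }
  walk(l1$initial, l2$initial)
}

# path-semantics model checking: recursive evaluation with reachability
# computed by explicit depth-first search, no fixpoints
check_oracle <- function(lts, f, state = lts$initial) {
  tr <- lts$transitions
  reach <- function(s) {
    seen <- s
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- setdiff(tr$to[tr$from %in% frontier], seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  labs_of <- function(patterns) {
    out <- character()
    for (l in patterns) {
      if (grepl("*", l, fixed = TRUE))
        out <- c(out, grep(utils::glob2rx(l), lts$alphabet, value = TRUE))
      else if (l %in% lts$alphabet) out <- c(out, l)
    }
    unique(out)
  }
  ev <- function(f, s) {
    switch(f$op,
      tt = TRUE,
      ff = FALSE,
      not = !ev(f$arg, s),
      and = ev(f$lhs, s) && ev(f$rhs, s),
      or = ev(f$lhs, s) || ev(f$rhs, s),
      dia = {
        A <- labs_of(f$labels)
        rows <- which(tr$from == s & tr$label %in% A)
        any(vapply(tr$to[rows], function(t2) ev(f$arg, t2), TRUE))
      },
      box = {
        A <- labs_of(f$labels)
        rows <- which(tr$from == s & tr$label %in% A)
        all(vapply(tr$to[rows], function(t2) ev(f$arg, t2), TRUE))
      },
      EX = {
        rows <- which(tr$from == s)
        any(vapply(tr$to[rows], function(t2) ev(f$arg, t2), TRUE))
      },
      EF = any(vapply(reach(s), function(t2) ev(f$arg, t2), TRUE)),
      AG = all(vapply(reach(s), function(t2) ev(f$arg, t2), TRUE)),
      stop("unknown op ", f$op)
    )
  }
  ev(f, state)
}

# random discretized exam over toy features, as a feature table
random_exam <- function(n_slices, features, patient_id = "p1",
                        plane = "coronal") {
  tbl <- tibble::tibble(patient_id = patient_id, plane = plane,
                        slice_index = seq_len(n_slices))
  for (f in features)
    tbl[[f]] <- sample(c("L", "M", "H"), n_slices, replace = TRUE)
  tbl
}

# random CCS model built from a random exam
random_model <- function(n_max = 3, k_max = 3) {
  n <- sample(n_max, 1)
  k <- sample(k_max, 1)
  feats <- paste0("TOY_Feat", letters[seq_len(k)])
  build_ccs_model(random_exam(n, feats))
}

# random formula AST over an alphabet, depth-bounded
random_formula <- function(alphabet, depth = 4) {
  pool <- c(alphabet, "H_*", "M_*", "L_*")
  labels <- function() sample(pool, sample(2, 1))
  go <- function(d) {
    ops <- if (d <= 0) c("tt", "ff")
           else c("tt", "ff", "not", "and", "or", "dia", "box",
                  "EF", "AG", "EX")
    op <- sample(ops, 1)
    switch(op,
      tt = list(op = "tt"),
      ff = list(op = "ff"),
      not = list(op = "not", arg = go(d - 1)),
      and = list(op = "and", lhs = go(d - 1), rhs = go(d - 1)),
      or = list(op = "or", lhs = go(d - 1), rhs = go(d - 1)),
      dia = list(op = "dia", labels = labels(), arg = go(d - 1)),
      box = list(op = "box", labels = labels(), arg = go(d - 1)),
      EF = list(op = "EF", arg = go(d - 1)),
      AG = list(op = "AG", arg = go(d - 1)),
      EX = list(op = "EX", arg = go(d - 1))
    )
  }
  structure(go(depth), class = "acdx_formula")
}

# direct slice-table scan: does any slice satisfy every constraint?
pattern_scan_oracle <- function(exam_tbl, pattern) {
  hits <- vapply(seq_len(nrow(exam_tbl)), function(i) {
    all(vapply(names(pattern$constraints), function(f) {
      exam_tbl[[f]][i] %in% pattern$constraints[[f]]
    }, TRUE))
  }, TRUE)
  sum(hits) >= pattern$min_slices
}
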