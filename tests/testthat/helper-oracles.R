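# Independent oracles used by the property-style suites. Each is written
# from scratch against the documented rules, on different data structures
# than the implementation it checks.

# --- label matching: brute-force scan --------------------------------------

oracle_match_terms <- function(query, index, kind = NULL, lang = NULL) {
  q <- tolower(query)
  grade_of <- function(label) {
    lab <- tolower(label)
    if (!nzchar(q)) return(1L)
    pos <- regexpr(q, lab, fixed = TRUE)[1]
    if (pos == 1) return(1L)
    if (pos > 1) {
      starts <- c(1L, gregexpr("\\s+", lab)[[1]] +
                    attr(gregexpr("\\s+", lab)[[1]], "match.length"))
      starts <- starts[starts > 0]
      for (st in starts) {
        if (substr(lab, st, st + nchar(q) - 1L) == q) {
          return(if (st == 1L) 1L else 2L)
        }
      }
      return(3L)
    }
    NA_integer_
  }
  lang_ok <- function(tag) {
    if (is.null(lang) || !nzchar(lang)) return(TRUE)
    tag == "" | tolower(sub("-.*", "", tag)) == tolower(sub("-.*", "", lang))
  }
  hits <- list()
  for (uri in names(index$terms)) {
    term <- index$terms[[uri]]
    if (!is.null(kind) && term$kind != kind) next
    labs <- term$labels
    if (nrow(labs) == 0) {
      labs <- data.frame(text = sub(".*[#/:]", "", uri), lang = "",
                         stringsAsFactors = FALSE)
    }
    best <- NA_integer_
    best_label <- NA_character_
    for (j in seq_len(nrow(labs))) {
      if (!lang_ok(labs$lang[j])) next
      g <- grade_of(labs$text[j])
      if (is.na(g)) next
      better <- is.na(best) || g < best ||
        (g == best && tolower(labs$text[j]) < tolower(best_label))
      if (better) { best <- g; best_label <- labs$text[j] }
    }
    if (is.na(best) && nzchar(q) && nrow(term$descriptions) > 0) {
      dok <- vapply(seq_len(nrow(term$descriptions)), function(j) {
        lang_ok(term$descriptions$lang[j]) &&
          grepl(q, tolower(term$descriptions$text[j]), fixed = TRUE)
      }, TRUE)
      if (any(dok) && any(vapply(seq_len(nrow(labs)), function(j)
        lang_ok(labs$lang[j]), TRUE))) {
        best <- 4L
      }
    }
    if (!is.na(best)) {
      hits[[length(hits) + 1L]] <- list(uri = uri, grade = best)
    }
  }
  hits
}

# --- graph neighborhood: explicit union-find -------------------------------

oracle_neighborhood <- function(triples, var) {
  n <- length(triples)
  if (n == 0) return(integer())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(i, j) parent[find(i)] <<- find(j)
  vars_of <- function(p) {
    out <- character()
    for (s in list(p$subject, p$predicate, p$object)) {
      if (s$kind == "variable") out <- c(out, s$value)
    }
    out
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && length(intersect(vars_of(triples[[i]]),
                                  vars_of(triples[[j]]))) > 0) {
      unite(i, j)
    }
  }
  with_var <- which(vapply(triples, function(p) var %in% vars_of(p), TRUE))
  if (length(with_var) == 0) return(integer())
  roots <- unique(vapply(with_var, find, 1L))
  which(vapply(seq_len(n), function(i) find(i) %in% roots, TRUE))
}

# --- type propagation: naive recompute-from-scratch closure ----------------

oracle_closure <- function(triples, records, ind_types) {
  pairs <- matrix(character(), ncol = 2)  # (variable, class)
  has_pair <- function(v, cl) any(pairs[, 1] == v & pairs[, 2] == cl)
  repeat {
    added <- FALSE
    for (p in triples) {
      if (p$object$kind != "variable" || p$predicate$kind != "iri") next
      subj_classes <-
        if (p$subject$kind == "iri") {
          ic <- ind_types[[p$subject$value]]
          if (is.null(ic)) character() else ic
        } else if (p$subject$kind == "variable") {
          pairs[pairs[, 1] == p$subject$value, 2]
        } else character()
      for (k in seq_len(nrow(records))) {
        r <- records[k, ]
        if (!nzchar(r$output_class)) next
        if (r$input_class %in% subj_classes &&
            r$property == p$predicate$value &&
            !has_pair(p$object$value, r$output_class)) {
          pairs <- rbind(pairs, c(p$object$value, r$output_class))
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  if (nrow(pairs) == 0) return(list())
  split(pairs[, 2], pairs[, 1])
}

# Random propagation instance: up to 10 triples / 10 records over a small
# universe of variables, individuals, properties and classes.
random_propagation_case <- function(seed) {
  set.seed(seed)
  vars <- paste0("v", 1:4)
  inds <- paste0("http://ex.org/i", 1:3)
  props <- paste0("http://ex.org/p", 1:4)
  classes <- paste0("http://ex.org/C", 1:4)
  node_v <- function(v) list(kind = "variable", value = v)
  node_i <- function(i) list(kind = "iri", value = i)
  n_tr <- sample(0:10, 1)
  triples <- lapply(seq_len(n_tr), function(k) {
    subj <- if (runif(1) < 0.5) node_v(sample(vars, 1)) else node_i(sample(inds, 1))
    list(subject = subj,
         predicate = node_i(sample(props, 1)),
         object = if (runif(1) < 0.7) node_v(sample(vars, 1))
           else node_i(sample(inds, 1)))
  })
  n_rec <- sample(0:10, 1)
  out_class <- sample(classes, n_rec, replace = TRUE)
  out_class[runif(n_rec) >= 0.8] <- ""
  records <- data.frame(
    id = sprintf("s%d", seq_len(n_rec)),
    input_class = sample(classes, n_rec, replace = TRUE),
    property = sample(props, n_rec, replace = TRUE),
    output_class = out_class,
    stringsAsFactors = FALSE)
  ind_types <- lapply(inds, function(i) sample(classes, sample(0:2, 1)))
  names(ind_types) <- inds
  ind_types <- ind_types[vapply(ind_types, length, 1L) > 0]
  list(triples = triples, records = records, ind_types = ind_types)
}

# --- grammar oracle: hand-written DFA over token roles ---------------------
#
# A full acceptor for the supported SELECT subset over a tiny vocabulary.
# States carry the grammatical position a content token would fill; NA marks
# states where only punctuation may follow.

oracle_vocab <- function() {
  data.frame(
    token = c("PREFIX", "SELECT", "WHERE", "FROM", "ex:",
              "<http://ex.org/x>", "?x", "?y", "\"lit\"",
              "{", "}", ".", ";", ","),
    role = c("kwPREFIX", "kwSELECT", "kwWHERE", "kwFROM", "pname",
             "iri", "var", "var", "literal",
             "lbrace", "rbrace", "dot", "semi", "comma"),
    stringsAsFactors = FALSE)
}

oracle_step <- function(state, role) {
  tr <- switch(state,
    q0 = c(kwPREFIX = "q1", kwSELECT = "q4"),
    q1 = c(pname = "q2"),
    q2 = c(iri = "q0"),
    q4 = c(var = "q5"),
    q5 = c(var = "q5", kwFROM = "q6", kwWHERE = "q8"),
    q6 = c(iri = "q7"),
    q7 = c(kwFROM = "q6", kwWHERE = "q8"),
    q8 = c(lbrace = "q9"),
    q9 = c(var = "q10", iri = "q10", rbrace = "q13"),
    q10 = c(var = "q11", iri = "q11"),
    q11 = c(var = "q12", iri = "q12", literal = "q12"),
    q12 = c(dot = "q9", semi = "q10", comma = "q11", rbrace = "q13"),
    q13 = c(),
    c())
  if (role %in% names(tr)) unname(tr[[role]]) else NA_character_
}

# Expected completion position per state; NA where no content token fits.
oracle_position <- function(state) {
  switch(state,
    q0 = "KEYWORD", q1 = "PREFIX_NAME", q2 = "PREFIX_IRI",
    q4 = "SELECT_VAR", q5 = "SELECT_VAR", q6 = "FROM_IRI",
    q7 = "KEYWORD", q9 = "SUBJECT", q10 = "PREDICATE", q11 = "OBJECT",
    NA_character_)
}

# All viable token sequences (prefixes of valid queries) up to max_len
# tokens, with the oracle state each one ends in.
oracle_enumerate <- function(max_len = 8) {
  vocab <- oracle_vocab()
  frontier <- list(list(tokens = character(), state = "q0"))
  out <- frontier
  for (depth in seq_len(max_len)) {
    nxt <- list()
    for (pf in frontier) {
      for (k in seq_len(nrow(vocab))) {
        st <- oracle_step(pf$state, vocab$role[k])
        if (!is.na(st)) {
          nxt[[length(nxt) + 1L]] <-
            list(tokens = c(pf$tokens, vocab$token[k]), state = st)
        }
      }
    }
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}
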