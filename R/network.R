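# Synchronous Boolean networks: representation, state transition,
# trajectory simulation, attractor detection, uniform sampling of concrete
# networks from candidate function sets, and a plain-text rule-file format.

#' Construct a synchronous Boolean network
#'
#' One fully defined Boolean function per gene; don't-cares are not allowed
#' here (instantiate them via [sample_network()]).
#'
#' @param functions List (one element per gene) of functions as produced by
#'   the inference module: each a list with `inputs` (gene indices,
#'   inputs\[1\] = most significant truth-table bit) and `table`
#'   (2^k entries in \{0, 1\}).
#' @param gene_ids Character vector of node names.
#' @return Object of class `boolean_network`.
#' @export
boolean_network <- function(functions, gene_ids = NULL) {
  n <- length(functions)
  if (n == 0L) stop("network must have at least one node", call. = FALSE)
  gene_ids <- gene_ids %||% paste0("g", seq_len(n))
  if (length(gene_ids) != n) stop("gene_ids length mismatch", call. = FALSE)
  for (f in functions) {
    k <- length(f$inputs)
    if (k > 0 && (any(f$inputs < 1L) || any(f$inputs > n))) {
      stop("function input index out of range", call. = FALSE)
    }
    if (length(f$table) != 2^k || anyNA(f$table) ||
        !all(f$table %in% c(0L, 1L))) {
      stop("truth table must be fully defined with 2^k 0/1 entries",
           call. = FALSE)
    }
  }
  structure(list(gene_ids = gene_ids, functions = functions),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Synchronous Boolean network:", length(x$gene_ids), "nodes\n")
  k <- vapply(x$functions, function(f) length(f$inputs), numeric(1))
  cat("  in-degrees: min", min(k), " mean", round(mean(k), 2),
      " max", max(k), "\n")
  invisible(x)
}

#' Synchronous state transition
#'
#' Applies every node's transition function simultaneously to the same
#' source state: x(t+1) = (f1(x(t)), ..., fn(x(t))).
#'
#' @param net A `boolean_network`.
#' @param x 0/1 state vector of length n (position i = gene i).
#' @return The successor 0/1 state vector.
#' @export
bn_transition <- function(net, x) {
  stopifnot(inherits(net, "boolean_network"))
  x <- assert_bits(x)
  if (length(x) != length(net$gene_ids)) {
    stop("state length does not match the network", call. = FALSE)
  }
  vapply(net$functions, function(f) {
    k <- length(f$inputs)
    if (k == 0L) f$table[1L] else f$table[pattern_index(x[f$inputs], k)]
  }, integer(1))
}

# Batched transition: M is a states x genes 0/1 matrix; returns the matrix
# of successors. Used by the stability experiments.
bn_transition_matrix <- function(net, M) {
  out <- M
  for (g in seq_along(net$functions)) {
    f <- net$functions[[g]]
    k <- length(f$inputs)
    out[, g] <- if (k == 0L) {
      f$table[1L]
    } else {
      idx <- as.integer(M[, f$inputs, drop = FALSE] %*% bit_weights(k) + 1)
      f$table[idx]
    }
  }
  out
}

#' Simulate a synchronous trajectory
#'
#' @param net A `boolean_network`.
#' @param x0 Initial 0/1 state.
#' @param steps Number of transitions (>= 0).
#' @return (steps + 1) x n 0/1 matrix; row 1 is `x0`, row j+1 the j-th
#'   successor.
#' @export
bn_simulate <- function(net, x0, steps) {
  stopifnot(inherits(net, "boolean_network"), steps >= 0)
  x0 <- assert_bits(x0)
  traj <- matrix(0L, steps + 1L, length(x0),
                 dimnames = list(NULL, net$gene_ids))
  traj[1L, ] <- x0
  if (steps > 0) {
    for (j in seq_len(steps)) traj[j + 1L, ] <- bn_transition(net, traj[j, ])
  }
  traj
}

#' @rdname bn_simulate
#' @param object A `boolean_network` (S3 `simulate` method).
#' @param nsim Number of transitions.
#' @param seed Optional seed (trajectories are deterministic; the seed only
#'   matters when `x0` is omitted and drawn uniformly).
#' @param x0 Initial state; uniform random if omitted.
#' @param ... Unused.
#' @export
simulate.boolean_network <- function(object, nsim = 1, seed = NULL,
                                     x0 = NULL, ...) {
  set_seed_if(seed)
  if (is.null(x0)) {
    x0 <- sample(c(0L, 1L), length(object$gene_ids), replace = TRUE)
  }
  bn_simulate(object, x0, nsim)
}

#' Attractor reached from a start state
#'
#' Walks the (deterministic) synchronous dynamics from `x0` keeping a
#' visited map until a state repeats; the cycle from the first revisited
#' state onward is the attractor.
#'
#' @param net A `boolean_network`.
#' @param x0 Initial 0/1 state.
#' @param max_steps Walk budget; the default 2^n guarantees termination.
#' @return Object of class `bn_attractor`: `states` (cycle states as rows,
#'   in transition order), `length` (cycle length) and `transient` (steps
#'   from `x0` to cycle entry).
#' @export
find_attractor <- function(net, x0, max_steps = 2^length(net$gene_ids)) {
  stopifnot(inherits(net, "boolean_network"))
  x <- assert_bits(x0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  path <- vector("list", 64L)
  len <- 0L
  for (i in seq_len(max_steps + 1L)) {
    key <- state_key(x)
    j <- seen[[key]]
    if (!is.null(j)) {
      cyc <- do.call(rbind, path[j:len])
      colnames(cyc) <- net$gene_ids
      return(structure(list(states = cyc, length = len - j + 1L,
                            transient = j - 1L),
                       class = "bn_attractor"))
    }
    len <- len + 1L
    if (len > length(path)) path <- c(path, vector("list", length(path)))
    path[[len]] <- x
    seen[[key]] <- len
    x <- bn_transition(net, x)
  }
  stop("max_steps exceeded without revisiting a state", call. = FALSE)
}

#' @export
print.bn_attractor <- function(x, ...) {
  cat("Attractor: cycle length", x$length, " transient", x$transient, "\n")
  invisible(x)
}

#' Sample a concrete network from a candidate function set
#'
#' Draws, independently per gene, one candidate uniformly at random; any
#' don't-care entries of a drawn template are instantiated by independent
#' fair-coin draws. Deterministic for a fixed seed.
#'
#' @param fs A `bn_function_set` (every gene needs >= 1 candidate).
#' @param seed Optional integer seed.
#' @return A `boolean_network`.
#' @export
sample_network <- function(fs, seed = NULL) {
  stopifnot(inherits(fs, "bn_function_set"))
  if (any(lengths(fs$functions) == 0L)) {
    stop("every gene needs at least one candidate function", call. = FALSE)
  }
  set_seed_if(seed)
  functions <- lapply(fs$functions, function(cands) {
    f <- cands[[sample.int(length(cands), 1L)]]
    nas <- which(is.na(f$table))
    if (length(nas) > 0L) {
      f$table[nas] <- sample(c(0L, 1L), length(nas), replace = TRUE)
    }
    f
  })
  boolean_network(functions, fs$gene_ids)
}

## ---- rule-file format -----------------------------------------------------
## Tab-separated, three columns: target, function, undefined. The function
## column is a constant 0/1 or a sum of minterms over the operators ! & |
## and parentheses, inputs in truth-table order (most significant first);
## the undefined column lists 1-based truth-table rows that are don't-cares.
## A comment line `# genes: ...` fixes the node order so files round-trip.

function_expression <- function(f, gene_ids) {
  k <- length(f$inputs)
  nm <- gene_ids[f$inputs]
  if (k == 0L) return(as.character(f$table[1L]))
  rows1 <- which(f$table == 1L)
  if (length(rows1) == 0L) {
    # no defined 1-row: a contradiction term per input keeps the input
    # order recoverable while evaluating to constant 0
    return(paste(sprintf("(%s & !%s)", nm, nm), collapse = " & "))
  }
  terms <- vapply(rows1, function(r) {
    bits <- index_bits(r, k)
    lits <- ifelse(bits == 1L, nm, paste0("!", nm))
    paste0("(", paste(lits, collapse = " & "), ")")
  }, character(1))
  paste(terms, collapse = " | ")
}

rule_lines <- function(functions_by_gene, gene_ids) {
  lines <- c(paste0("# genes: ", paste(gene_ids, collapse = " ")),
             "target\tfunction\tundefined")
  for (g in seq_along(functions_by_gene)) {
    for (f in functions_by_gene[[g]]) {
      und <- which(is.na(f$table))
      lines <- c(lines, paste(gene_ids[g],
                              function_expression(f, gene_ids),
                              paste(und, collapse = ","),
                              sep = "\t"))
    }
  }
  lines
}

#' Write Boolean rules to a plain-text file
#'
#' One line per gene per candidate function, `target \\t function \\t
#' undefined`; see the package vignette for the grammar. Round-trips
#' losslessly through [read_rules()] / [read_boolean_network()].
#'
#' @param x A `boolean_network` or `bn_function_set`.
#' @param path Output file path.
#' @export
write_rules <- function(x, path) {
  if (inherits(x, "boolean_network")) {
    fb <- lapply(x$functions, list)
    writeLines(rule_lines(fb, x$gene_ids), path)
  } else if (inherits(x, "bn_function_set")) {
    writeLines(rule_lines(x$functions, x$gene_ids), path)
  } else {
    stop("x must be a boolean_network or bn_function_set", call. = FALSE)
  }
  invisible(path)
}

parse_rule_expression <- function(expr, gene_ids) {
  expr <- trimws(expr)
  if (expr == "0" || expr == "1") {
    return(new_bn_function(integer(0), as.integer(expr)))
  }
  token_re <- "[A-Za-z0-9_.]+|[!&|()]"
  tokens <- regmatches(expr, gregexpr(token_re, expr))[[1]]
  if (gsub(token_re, "", gsub("[[:space:]]", "", expr)) != "") {
    stop("unparsable rule expression: ", expr, call. = FALSE)
  }
  is_id <- grepl("^[A-Za-z0-9_.]+$", tokens) & !(tokens %in% c("!", "&", "|", "(", ")"))
  ids <- tokens[is_id]
  if (!all(ids %in% gene_ids)) {
    stop("unknown gene in rule: ", paste(setdiff(ids, gene_ids), collapse = ", "),
         call. = FALSE)
  }
  inputs_nm <- unique(ids) # first-appearance order = truth-table order
  k <- length(inputs_nm)
  vars <- paste0(".v", match(ids, inputs_nm))
  tokens[is_id] <- vars
  lang <- str2lang(paste(tokens, collapse = " "))
  table <- vapply(seq_len(2^k), function(r) {
    bits <- index_bits(r, k)
    env <- stats::setNames(as.list(as.logical(bits)), paste0(".v", seq_len(k)))
    as.integer(eval(lang, env))
  }, integer(1))
  new_bn_function(match(inputs_nm, gene_ids), table)
}

#' Read Boolean rules from a plain-text file
#'
#' Inverse of [write_rules()]. Returns a `bn_function_set`; use
#' [read_boolean_network()] when the file holds exactly one fully defined
#' function per gene.
#'
#' @param path Rule file path.
#' @return A `bn_function_set`.
#' @export
read_rules <- function(path) {
  lines <- readLines(path)
  gline <- grep("^# genes:", lines, value = TRUE)
  if (length(gline) != 1L) stop("missing '# genes:' header", call. = FALSE)
  gene_ids <- strsplit(sub("^# genes: *", "", gline), " +")[[1]]
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  body <- body[-1L] # column header
  functions <- stats::setNames(rep(list(list()), length(gene_ids)), gene_ids)
  for (ln in body) {
    parts <- strsplit(ln, "\t")[[1]]
    target <- parts[1]
    if (!target %in% gene_ids) stop("unknown target gene: ", target, call. = FALSE)
    f <- parse_rule_expression(parts[2], gene_ids)
    if (length(parts) >= 3L && nzchar(trimws(parts[3]))) {
      und <- as.integer(strsplit(parts[3], ",")[[1]])
      f$table[und] <- NA_integer_
    }
    functions[[target]] <- c(functions[[target]], list(f))
  }
  if (any(lengths(functions) == 0L)) {
    stop("file does not define every gene", call. = FALSE)
  }
  structure(
    list(gene_ids = gene_ids, functions = unname(functions),
         errors = stats::setNames(rep(NA_real_, length(gene_ids)), gene_ids),
         dependencies = dependencies_of(unname(functions), gene_ids)),
    class = "bn_function_set"
  )
}

dependencies_of <- function(functions, gene_ids) {
  deps <- do.call(rbind, lapply(seq_along(functions), function(g) {
    regs <- sort(unique(unlist(lapply(functions[[g]], `[[`, "inputs"))))
    if (length(regs) == 0L) return(NULL)
    data.frame(regulator = gene_ids[regs], target = gene_ids[g],
               stringsAsFactors = FALSE)
  }))
  if (is.null(deps)) data.frame(regulator = character(0), target = character(0)) else deps
}

#' @rdname read_rules
#' @return For `read_boolean_network()`, a `boolean_network`.
#' @export
read_boolean_network <- function(path) {
  fs <- read_rules(path)
  if (any(lengths(fs$functions) != 1L)) {
    stop("file has more than one function for some gene", call. = FALSE)
  }
  boolean_network(lapply(fs$functions, `[[`, 1L), fs$gene_ids)
}
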