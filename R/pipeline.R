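# End-to-end study: preprocess -> binarize (pooled threshold) -> group
# split -> best-fit reconstruction per group -> stability experiments ->
# group comparison, with a manifest that makes every number recomputable.

#' Preprocess a gene-by-sample expression matrix
#'
#' Collapses duplicate gene rows by geometric mean (values must be strictly
#' positive wherever a gene is duplicated), averages duplicate same-age
#' samples within a group arithmetically on the real-valued scale, orders
#' columns by age within group, and optionally restricts to a gene list
#' (the retained count is reported via `message()`).
#'
#' @param x Numeric matrix, rownames = gene identifiers.
#' @param ages Numeric per-column ages.
#' @param groups Character per-column group labels.
#' @param gene_list Optional character vector of identifiers to keep.
#' @return List with `expression` (collapsed, ordered matrix), `ages`,
#'   `groups`.
#' @export
preprocess_expression <- function(x, ages, groups, gene_list = NULL) {
  if (!is.matrix(x) || is.null(rownames(x))) {
    stop("x must be a matrix with gene rownames", call. = FALSE)
  }
  if (length(ages) != ncol(x) || length(groups) != ncol(x)) {
    stop("ages and groups must match the columns of x", call. = FALSE)
  }
  # duplicate gene rows -> geometric mean
  ids <- rownames(x)
  if (anyDuplicated(ids)) {
    dup_ids <- unique(ids[duplicated(ids)])
    for (id in dup_ids) {
      if (any(x[ids == id, ] <= 0)) {
        stop("gene ", id, " has non-positive values; geometric mean undefined",
             call. = FALSE)
      }
    }
    x <- do.call(rbind, lapply(unique(ids), function(id) {
      rows <- x[ids == id, , drop = FALSE]
      if (nrow(rows) == 1L) rows[1, ] else exp(colMeans(log(rows)))
    }))
    rownames(x) <- unique(ids)
  }
  # duplicate (group, age) columns -> arithmetic mean
  key <- paste(groups, ages, sep = "\r")
  if (anyDuplicated(key)) {
    uk <- unique(key)
    merged <- vapply(uk, function(k) rowMeans(x[, key == k, drop = FALSE]),
                     numeric(nrow(x)))
    ages <- ages[match(uk, key)]
    groups <- groups[match(uk, key)]
    x <- matrix(merged, nrow = nrow(x),
                dimnames = list(rownames(x), paste(groups, ages, sep = "_")))
  }
  # order by age within group (groups keep their first-appearance order)
  ord <- order(match(groups, unique(groups)), ages)
  x <- x[, ord, drop = FALSE]
  ages <- ages[ord]
  groups <- groups[ord]
  if (!is.null(gene_list)) {
    keep <- intersect(gene_list, rownames(x))
    message(length(keep), " of ", length(gene_list),
            " listed genes found in the matrix")
    x <- x[keep, , drop = FALSE]
  }
  list(expression = x, ages = ages, groups = groups)
}

#' Run the full two-group stability study
#'
#' The fitting function of the package: binarizes the pooled matrix with one
#' threshold per gene, drops genes that are not significantly binarizable,
#' splits the binary series by group, reconstructs candidate Boolean
#' functions per group by the best-fit algorithm, runs the perturbation
#' protocol on networks sampled from each group's candidate set, and
#' compares the two groups' per-network mean Hamming distances by Wilcoxon
#' rank-sum tests.
#'
#' @param x Numeric genes x samples matrix (rownames = gene ids, columns in
#'   time order; preprocess with [preprocess_expression()] first if needed).
#' @param groups Per-column group labels (exactly two distinct values; the
#'   first-appearance order fixes the group order in all outputs).
#' @param alpha Binarization significance level (default 0.05).
#' @param n_bootstrap Bootstrap null samples per gene (default 1000).
#' @param max_k Maximal input-set size for best-fit (default 5).
#' @param expansion_cap Don't-care expansion cap (default 1024).
#' @param n_networks,n_states,n_flip_bits,horizons,state_classes Perturbation
#'   protocol; see [stability_experiment()].
#' @param seed Integer master seed; every stage's randomness derives from it.
#' @return Object of class `bn_study` with components `binarization`,
#'   `binary` (retained genes x samples), `function_sets`, `stability`,
#'   `comparison`, `mean_inputs`, `manifest`.
#' @export
run_study <- function(x, groups, alpha = 0.05, n_bootstrap = 1000L,
                      max_k = 5L, expansion_cap = 1024L,
                      n_networks = 1000L, n_states = 1000L, n_flip_bits = 1L,
                      horizons = c(1L, 5L),
                      state_classes = c("random", "successor", "attractor"),
                      seed = 1L) {
  if (length(groups) != ncol(x)) stop("groups must match columns", call. = FALSE)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups are required", call. = FALSE)
  set.seed(seed)
  stage_seeds <- draw_seeds(4L)
  bin <- binarize_matrix(x, alpha, n_bootstrap, seed = stage_seeds[1])
  if (nrow(bin$binary) == 0L) {
    stop("stage binarize: no gene is significantly binarizable", call. = FALSE)
  }
  fs <- list()
  stab <- list()
  for (i in seq_along(lev)) {
    g <- lev[i]
    bg <- bin$binary[, groups == g, drop = FALSE]
    fs[[g]] <- tryCatch(
      reconstruct(bg, max_k = max_k, expansion_cap = expansion_cap),
      error = function(e) stop("stage infer (", g, "): ",
                               conditionMessage(e), call. = FALSE)
    )
    stab[[g]] <- tryCatch(
      stability_experiment(fs[[g]], n_networks, n_states, n_flip_bits,
                           horizons, state_classes,
                           seed = stage_seeds[1L + i]),
      error = function(e) stop("stage stability (", g, "): ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  comparison <- compare_stability(stab[[lev[1]]], stab[[lev[2]]])
  manifest <- list(
    package = "bnstability",
    package_version = as.character(utils::packageVersion("bnstability")),
    r_version = R.version.string,
    parameters = list(alpha = alpha, n_bootstrap = n_bootstrap,
                      max_k = max_k, expansion_cap = expansion_cap,
                      n_networks = n_networks, n_states = n_states,
                      n_flip_bits = n_flip_bits, horizons = horizons,
                      state_classes = state_classes, seed = seed,
                      groups = lev),
    variants = list(
      discontinuity_score = "jump height / (two-segment SSE at the break + machine eps)",
      threshold_aggregation = "lower median of strongest-break sorted ranks over d = 1..n-2; midpoint of flanking sorted values",
      significance_test = "stand-in: seeded bootstrap, uniform null on [min, max], statistic = threshold jump / range",
      error_definition = "misclassified pairs with multiplicity: sum over patterns of min(#true, #false)",
      attractor_state = "uniform member of the cycle reached from a uniform draw"
    )
  )
  structure(
    list(binarization = bin, binary = bin$binary, groups = groups,
         function_sets = fs, stability = stab, comparison = comparison,
         mean_inputs = vapply(fs, mean_inputs_per_function, numeric(1)),
         manifest = manifest),
    class = "bn_study"
  )
}

#' @export
print.bn_study <- function(x, ...) {
  lev <- x$manifest$parameters$groups
  cat("Two-group Boolean network stability study\n")
  cat("  genes:", length(x$binarization$gene_ids), "->",
      sum(x$binarization$retained), "significantly binarizable (p <",
      x$binarization$alpha, ")\n")
  for (g in lev) {
    cat("  ", g, ": ", nrow(x$function_sets[[g]]$dependencies),
        " dependencies, mean inputs/function ",
        round(x$mean_inputs[[g]], 3), "\n", sep = "")
  }
  cat("\nMean normalized Hamming distance per (class, horizon):\n")
  tabs <- lapply(lev, function(g) {
    t <- x$stability[[g]]$table
    stats::setNames(t[c("class", "horizon", "mean")],
                    c("class", "horizon", g))
  })
  print(merge(tabs[[1]], tabs[[2]], by = c("class", "horizon")),
        row.names = FALSE, digits = 3)
  cat("\nGroup comparison (Wilcoxon rank-sum):\n")
  print.data.frame(x$comparison[c("class", "horizon", "p_value")],
                   row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.bn_study <- function(object, ...) {
  lev <- object$manifest$parameters$groups
  out <- do.call(rbind, lapply(lev, function(g) {
    cbind(group = g, object$stability[[g]]$table)
  }))
  out
}

#' @export
plot.bn_study <- function(x, ...) {
  lev <- x$manifest$parameters$groups
  d1 <- x$stability[[lev[1]]]$per_network
  d2 <- x$stability[[lev[2]]]$per_network
  cls <- dimnames(d1)[[2]]
  hrz <- dimnames(d1)[[3]]
  vals <- list()
  for (h in hrz) {
    for (cl in cls) {
      vals[[paste(cl, h, lev[1])]] <- d1[, cl, h]
      vals[[paste(cl, h, lev[2])]] <- d2[, cl, h]
    }
  }
  graphics::boxplot(vals, las = 2, ylab = "normalized Hamming distance",
                    col = rep(c("grey80", "grey50"), length.out = length(vals)),
                    main = "Per-network mean damage by group", ...)
  invisible(x)
}

## ---- tabular output -------------------------------------------------------

#' Write study artifacts to a directory
#'
#' Emits the binarization table (threshold and p-value per gene), per-group
#' rule files and adjacency TSVs, a function-count table, the
#' stability summary in a wide per-class layout, the per-network averages,
#' the comparison report (JSON) and the run manifest (JSON).
#'
#' @param study A `bn_study`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_study_outputs <- function(study, dir) {
  stopifnot(inherits(study, "bn_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lev <- study$manifest$parameters$groups
  bin <- study$binarization
  utils::write.table(
    data.frame(gene = bin$gene_ids, threshold = bin$thresholds,
               p_value = bin$p_values, retained = bin$retained),
    file.path(dir, "binarization.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    cbind(gene = rownames(study$binary), as.data.frame(study$binary)),
    file.path(dir, "binarized_matrix.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- list()
  for (g in lev) {
    fs <- study$function_sets[[g]]
    write_rules(fs, file.path(dir, paste0("rules_", g, ".txt")))
    utils::write.table(
      cbind(fs$dependencies, group = g),
      file.path(dir, paste0("adjacency_", g, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    counts[[g]] <- function_counts(fs)
  }
  utils::write.table(
    data.frame(gene = names(counts[[1]]),
               stats::setNames(as.data.frame(counts), paste0("n_functions_", lev))),
    file.path(dir, "function_counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  stab_tab <- do.call(rbind, lapply(lev, function(g) {
    cbind(group = g, study$stability[[g]]$table)
  }))
  write_stability_table(stab_tab, file.path(dir, "stability.tsv"))
  per_net <- do.call(rbind, lapply(lev, function(g) {
    d <- study$stability[[g]]$per_network
    do.call(rbind, lapply(dimnames(d)[[2]], function(cl) {
      do.call(rbind, lapply(dimnames(d)[[3]], function(h) {
        data.frame(group = g, class = cl, horizon = h,
                   network = seq_len(dim(d)[1]), mean_distance = d[, cl, h])
      }))
    }))
  }))
  utils::write.table(per_net, file.path(dir, "per_network.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(comparison = study$comparison,
         mean_inputs = as.list(study$mean_inputs)),
    file.path(dir, "comparison.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# Wide layout: rows = state classes, columns = group x horizon x min/max/mean.
write_stability_table <- function(stab_tab, path) {
  classes <- unique(stab_tab$class)
  cols <- list(class = classes)
  for (g in unique(stab_tab$group)) {
    for (h in unique(stab_tab$horizon)) {
      sel <- stab_tab[stab_tab$group == g & stab_tab$horizon == h, ]
      sel <- sel[match(classes, sel$class), ]
      cols[[paste(g, paste0("h", h), "min", sep = "_")]] <- sel$min
      cols[[paste(g, paste0("h", h), "max", sep = "_")]] <- sel$max
      cols[[paste(g, paste0("h", h), "mean", sep = "_")]] <- sel$mean
    }
  }
  utils::write.table(as.data.frame(cols), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---- file formats ---------------------------------------------------------

#' Read an expression matrix from TSV/CSV
#'
#' First column = gene identifier, remaining columns = samples in time
#' order. The delimiter is inferred from the extension (`.csv` -> comma,
#' otherwise tab).
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read a sample sheet (sample, group, age)
#'
#' @param path TSV with columns `sample`, `group`, `age`.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample", "group", "age")
  if (!all(need %in% names(df))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a one-identifier-per-line gene list
#' @param path File path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !grepl("^#", x)]
}

#' Parse a GEO series-matrix file
#'
#' Extracts the numeric expression table between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers of a
#' (possibly gzipped) series-matrix file.
#'
#' @param path Path to a series-matrix file.
#' @return Numeric matrix, probe/gene identifiers as rownames, sample
#'   accessions as colnames.
#' @export
read_series_matrix <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
    stop("no series-matrix table found in ", path, call. = FALSE)
  }
  tc <- textConnection(lines[(beg + 1L):(end - 1L)])
  on.exit(close(tc), add = TRUE)
  df <- utils::read.table(tc, header = TRUE, sep = "\t", quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Fetch and cache a GEO series-matrix file
#'
#' Convenience download of `<accession>_series_matrix.txt.gz` from the NCBI
#' GEO FTP mirror. Requires network access; every analysis function in the
#' package works on a local matrix, so the full test suite runs with the
#' network disabled.
#'
#' @param accession GEO series accession, e.g. `"GSE362"`.
#' @param destdir Cache directory (default `tempdir()`).
#' @return Path to the downloaded (or cached) file.
#' @export
fetch_geo_series_matrix <- function(accession = "GSE362",
                                    destdir = tempdir()) {
  stub <- sub("[0-9]{1,3}$", "nnn", accession)
  url <- sprintf(
    "https://ftp.ncbi.nlm.nih.gov/geo/series/%s/%s/matrix/%s_series_matrix.txt.gz",
    stub, accession, accession)
  dest <- file.path(destdir, paste0(accession, "_series_matrix.txt.gz"))
  if (!file.exists(dest)) {
    utils::download.file(url, dest, mode = "wb", quiet = TRUE)
  }
  dest
}

#' The 22-gene NF-kB signaling panel
#'
#' Gene symbols and Entrez identifiers of the 22 significantly binarizable
#' NF-kB signaling genes used throughout the documentation; shipped as a
#' plain-text fixture in `inst/extdata/nfkb22_entrez.tsv`.
#'
#' @return data.frame with columns `symbol` and `entrez`.
#' @export
nfkb_gene_panel <- function() {
  path <- system.file("extdata", "nfkb22_entrez.tsv", package = "bnstability")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
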