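# Readers and writers for the on-disk formats: a multilayer edge list (TSV
# with header source/target/layer/weight) plus a JSON sidecar schema, a
# node-attribute CSV plus schema, and a dense dataset directory used for
# fixtures and fit artifacts. Sparse conventions: Bernoulli and Poisson
# layers treat unlisted pairs as observed zeros; Gaussian layers treat them
# as unobserved, since a real-valued "zero" would be informative.

#' Write a multilayer edge list and its schema
#'
#' @param network a `typed_network`.
#' @param path TSV output path.
#' @param schema_path JSON sidecar path.
#' @export
write_multilayer_edgelist <- function(network, path, schema_path) {
  rows <- list()
  for (l in seq_len(network$L)) {
    fam <- network$layers[[l]]$family
    m <- network$mask[[l]]
    keep <- if (fam == "gaussian") m else (m & network$A[[l]] != 0)
    idx <- which(keep, arr.ind = TRUE)
    if (nrow(idx)) {
      rows[[l]] <- data.frame(
        source = network$node_ids[idx[, 1L]],
        target = network$node_ids[idx[, 2L]],
        layer = network$layers[[l]]$index,
        weight = format(network$A[[l]][keep], digits = 17, trim = TRUE,
                        scientific = FALSE))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), target = character(),
               layer = integer(), weight = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  schema <- list(
    nodes = network$node_ids,
    layers = lapply(network$layers, function(s) {
      out <- list(layer = s$index, family = s$family, directed = s$directed)
      if (!is.null(s$sigma2)) out$sigma2 <- s$sigma2
      out
    }))
  jsonlite::write_json(schema, schema_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multilayer edge list with a schema sidecar
#'
#' Node IDs are strings; with no `nodes` entry in the schema they are
#' mapped to contiguous indices in order of first appearance. Unlisted
#' pairs are observed zeros in Bernoulli/Poisson layers and unobserved in
#' Gaussian layers. Duplicate `(source, target, layer)` rows, unknown layer
#' labels and out-of-domain weights are errors naming the line.
#'
#' @param path TSV edge list.
#' @param schema_path JSON schema.
#' @return a `typed_network`.
#' @export
read_multilayer_edgelist <- function(path, schema_path) {
  schema <- jsonlite::read_json(schema_path, simplifyVector = FALSE)
  layers <- lapply(schema$layers, function(s)
    layer_spec(s$layer, s$family, directed = isTRUE(s$directed),
               sigma2 = s$sigma2))
  layer_ids <- vapply(layers, function(s) s$index, 1L)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "integer", "character"))
  node_ids <- if (!is.null(schema$nodes)) unlist(schema$nodes) else
    unique(c(rbind(df$source, df$target)))
  N <- length(node_ids)
  key <- paste(df$source, df$target, df$layer)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1L]
    stop("duplicate (source, target, layer) at line ", dup + 1L)
  }
  A <- lapply(seq_along(layers), function(l) matrix(0, N, N))
  mask <- lapply(seq_along(layers), function(l) {
    m <- matrix(layers[[l]]$family != "gaussian", N, N)
    if (!layers[[l]]$directed) m[lower.tri(m, diag = TRUE)] <- FALSE
    diag(m) <- FALSE
    m
  })
  si <- match(df$source, node_ids)
  ti <- match(df$target, node_ids)
  if (anyNA(si) || anyNA(ti))
    stop("edge references a node missing from the schema node list (line ",
         which(is.na(si) | is.na(ti))[1L] + 1L, ")")
  for (r in seq_len(nrow(df))) {
    l <- match(df$layer[r], layer_ids)
    if (is.na(l)) stop("unknown layer label '", df$layer[r], "' at line ", r + 1L)
    w <- suppressWarnings(as.numeric(df$weight[r]))
    fam <- layers[[l]]$family
    if (is.na(w)) stop("missing or non-numeric weight at line ", r + 1L)
    ok <- switch(fam,
      bernoulli = w %in% c(0, 1),
      poisson = w >= 0 && w == round(w),
      gaussian = is.finite(w))
    if (!ok) stop("weight ", df$weight[r], " outside ", fam,
                  " domain at line ", r + 1L)
    i <- si[r]; j <- ti[r]
    if (!layers[[l]]$directed && i > j) { tmp <- i; i <- j; j <- tmp }
    A[[l]][i, j] <- w
    mask[[l]][i, j] <- TRUE
  }
  typed_network(A, layers, mask = mask, node_ids = node_ids)
}

#' Write a node-attribute table and its schema
#'
#' @param table an `attribute_table`.
#' @param path CSV output path.
#' @param schema_path JSON sidecar path; categorical attributes record
#'   their category labels in order, so labels round-trip.
#' @export
write_attribute_table <- function(table, path, schema_path) {
  df <- data.frame(node = table$node_ids, stringsAsFactors = FALSE)
  for (p in seq_len(table$P)) {
    a <- table$attrs[[p]]
    col <- sprintf("attr%d", a$index)
    v <- table$X[, p]
    v[!table$mask[, p]] <- NA
    df[[col]] <- if (a$family == "categorical") {
      ifelse(is.na(v), "", sprintf("c%d", v))
    } else {
      ifelse(is.na(v), "", format(v, digits = 17, trim = TRUE, scientific = FALSE))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  schema <- list(attributes = lapply(table$attrs, function(a) {
    out <- list(attribute = a$index, family = a$family)
    if (a$family == "categorical") out$categories <- sprintf("c%d", seq_len(a$Z))
    if (!is.null(a$sigma2)) out$sigma2 <- a$sigma2
    out
  }))
  jsonlite::write_json(schema, schema_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a node-attribute table with a schema sidecar
#'
#' Categorical labels are mapped to integer codes by the schema-declared
#' category order; labels outside it raise an error naming the row. Empty
#' cells are masked.
#'
#' @param path CSV with a header row, one row per node, first column the
#'   node ID.
#' @param schema_path JSON schema.
#' @param node_ids optional node ordering (e.g. from the network); rows are
#'   matched to it by ID.
#' @return an `attribute_table`.
#' @export
read_attribute_table <- function(path, schema_path, node_ids = NULL) {
  schema <- jsonlite::read_json(schema_path, simplifyVector = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  if (is.null(node_ids)) node_ids <- df$node
  ord <- match(node_ids, df$node)
  if (anyNA(ord)) stop("attribute table is missing node(s): ",
                       paste(node_ids[is.na(ord)], collapse = ", "))
  attrs <- list()
  N <- length(node_ids)
  X <- matrix(NA_real_, N, length(schema$attributes))
  for (p in seq_along(schema$attributes)) {
    s <- schema$attributes[[p]]
    col <- df[[sprintf("attr%d", s$attribute)]][ord]
    if (s$family == "categorical") {
      cats <- unlist(s$categories)
      attrs[[p]] <- attribute_spec(s$attribute, "categorical", Z = length(cats))
      code <- match(col, cats)
      bad <- which(!is.na(col) & col != "" & is.na(code))
      if (length(bad)) stop("attribute ", s$attribute, ": label '", col[bad[1L]],
                            "' not among declared categories (row ", bad[1L] + 1L, ")")
      X[, p] <- code
    } else {
      attrs[[p]] <- attribute_spec(s$attribute, s$family, sigma2 = s$sigma2)
      X[, p] <- suppressWarnings(as.numeric(ifelse(col == "", NA, col)))
    }
  }
  attribute_table(X, attrs, node_ids = node_ids)
}

#' Write a dataset directory (edge list, attributes, schemas, ground truth)
#'
#' The container format used by fixtures and the command-line interface:
#' `network.tsv` + `network_schema.json`, `attributes.csv` +
#' `attributes_schema.json`, explicit `mask_layer<l>.csv` files for every
#' layer (so cross-validation hold-outs survive a round trip), and, when a
#' ground-truth state is given, its blocks as CSV plus the softmax
#' memberships.
#'
#' @param dataset list with `network`, `table` and optionally `state` (as
#'   from [sample_dataset()]).
#' @param dir output directory (created).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_multilayer_edgelist(dataset$network, file.path(dir, "network.tsv"),
                            file.path(dir, "network_schema.json"))
  write_attribute_table(dataset$table, file.path(dir, "attributes.csv"),
                        file.path(dir, "attributes_schema.json"))
  for (l in seq_len(dataset$network$L))
    write_matrix(dataset$network$mask[[l]] * 1L,
                 file.path(dir, sprintf("mask_layer%d.csv", l)))
  if (!is.null(dataset$state)) {
    st <- dataset$state
    write_matrix(st$U, file.path(dir, "truth_U.csv"))
    if (st$directed) write_matrix(st$V, file.path(dir, "truth_V.csv"))
    for (l in seq_along(st$W))
      write_matrix(st$W[[l]], file.path(dir, sprintf("truth_W%d.csv", l)))
    write_matrix(st$H, file.path(dir, "truth_H.csv"))
    write_matrix(softmax_rows(st$U), file.path(dir, "truth_membership.csv"))
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `network`, `table` and, when present, the
#'   ground-truth `state`.
#' @export
read_dataset <- function(dir) {
  network <- read_multilayer_edgelist(file.path(dir, "network.tsv"),
                                      file.path(dir, "network_schema.json"))
  for (l in seq_len(network$L)) {
    mf <- file.path(dir, sprintf("mask_layer%d.csv", l))
    if (file.exists(mf)) network$mask[[l]] <- read_matrix(mf) == 1
  }
  table <- read_attribute_table(file.path(dir, "attributes.csv"),
                                file.path(dir, "attributes_schema.json"),
                                node_ids = network$node_ids)
  out <- list(network = network, table = table)
  if (file.exists(file.path(dir, "truth_U.csv"))) {
    U <- read_matrix(file.path(dir, "truth_U.csv"))
    directed <- file.exists(file.path(dir, "truth_V.csv"))
    V <- if (directed) read_matrix(file.path(dir, "truth_V.csv")) else NULL
    W <- lapply(seq_len(network$L), function(l)
      read_matrix(file.path(dir, sprintf("truth_W%d.csv", l))))
    H <- read_matrix(file.path(dir, "truth_H.csv"))
    out$state <- latent_state(U = U, V = V, W = W, H = H, directed = directed)
    out$membership <- softmax_rows(U)
  }
  out
}

# full-precision headerless CSV for numeric matrices
write_matrix <- function(M, path) {
  utils::write.table(format(M, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

read_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Write fit artifacts (MAP state, trace, manifest, posterior)
#'
#' @param fit a `hamnet_fit`.
#' @param dir output directory.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- fit$state
  write_matrix(st$U, file.path(dir, "map_U.csv"))
  if (st$directed) write_matrix(st$V, file.path(dir, "map_V.csv"))
  for (l in seq_along(st$W))
    write_matrix(st$W[[l]], file.path(dir, sprintf("map_W%d.csv", l)))
  if (ncol(st$H)) write_matrix(st$H, file.path(dir, "map_H.csv"))
  utils::write.csv(data.frame(iteration = seq_along(fit$trace),
                              objective = fit$trace),
                   file.path(dir, "trace.csv"), row.names = FALSE)
  manifest <- list(config = unclass(fit$config), directed = fit$directed,
                   objective = fit$objective, converged = fit$converged,
                   package_version = as.character(utils::packageVersion("hamnet")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(fit$posterior)) {
    write_matrix(fit$posterior$U_mean, file.path(dir, "posterior_U_mean.csv"))
    write_matrix(fit$posterior$U_var, file.path(dir, "posterior_U_var.csv"))
    if (!is.null(fit$posterior$V_mean)) {
      write_matrix(fit$posterior$V_mean, file.path(dir, "posterior_V_mean.csv"))
      write_matrix(fit$posterior$V_var, file.path(dir, "posterior_V_var.csv"))
    }
  }
  invisible(dir)
}
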