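# Plain-text input/output for every artifact. All tables are tab-separated
# with '.' decimal and POSIX newlines; type and group indices are 0-based
# in files (the 1-based indexing used in R is a display concern).

fmt_num <- function(x) sprintf("%.17g", x)  # lossless double round-trip

#' Write / read a payoff matrix
#'
#' The matrix is written as plain tab-separated text, one row per line, no
#' header, with full float precision (write-then-read reproduces the
#' entries exactly). When the matrix carries generation metadata a sidecar
#' key-value file `<path>.meta` (keys `d`, `mu`, `sigma2`, `seed`) is
#' written and read back.
#'
#' @param A A [payoff_matrix()].
#' @param path File path.
#' @return `write_payoff_matrix` returns `path` invisibly;
#'   `read_payoff_matrix` returns a [payoff_matrix()].
#' @export
write_payoff_matrix <- function(A, path) {
  A <- as_payoff_matrix(A)
  lines <- apply(unclass(A), 1, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(lines, path)
  meta <- attr(A, "gen_meta")
  if (!is.null(meta)) {
    writeLines(c(paste0("d: ", nrow(A)),
                 paste0("mu: ", fmt_num(meta$mu)),
                 paste0("sigma2: ", fmt_num(meta$sigma2)),
                 paste0("seed: ", meta$seed)),
               paste0(path, ".meta"))
  }
  invisible(path)
}

#' @rdname write_payoff_matrix
#' @export
read_payoff_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty matrix file: ", path, call. = FALSE)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    stop("non-square matrix: ragged rows in ", path, call. = FALSE)
  }
  vals <- suppressWarnings(lapply(rows, as.numeric))
  if (any(vapply(vals, function(v) any(is.na(v)), logical(1)))) {
    stop("non-numeric field in matrix file ", path, call. = FALSE)
  }
  M <- do.call(rbind, vals)
  if (nrow(M) != ncol(M)) {
    stop("non-square matrix: ", nrow(M), " rows, ", ncol(M), " columns",
         call. = FALSE)
  }
  meta <- NULL
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    kv <- read_keyvalue(meta_path)
    meta <- list(mu = as.numeric(kv[["mu"]]),
                 sigma2 = as.numeric(kv[["sigma2"]]),
                 seed = suppressWarnings(as.integer(kv[["seed"]])))
  }
  payoff_matrix(M, gen_meta = meta)
}

read_keyvalue <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  kv <- lapply(parts, function(p) trimws(p[2]))
  names(kv) <- vapply(parts, function(p) trimws(p[1]), character(1))
  kv
}

#' Write / read a trajectory
#'
#' Tidy tab-separated table with header columns `event_clock`,
#' `group_index`, `type_index`, `count` (indices 0-based); only nonzero
#' counts are stored. Reading requires the run's configuration (or at
#' least `d` and `m`) to reconstruct the dense snapshots.
#'
#' @param traj A `sim_trajectory`.
#' @param path File path.
#' @param config The run's [sim_config()] (used by `read_trajectory` to
#'   size the snapshots; also re-attached to the returned object).
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `sim_trajectory` (with an empty event log, which is not
#'   serialized in the table).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "sim_trajectory"))
  df <- as.data.frame(traj)
  out <- data.table::data.table(event_clock = df$event_clock,
                                group_index = df$group - 1L,
                                type_index = df$type - 1L,
                                count = df$count)
  data.table::fwrite(out, path, sep = "\t", eol = "\n")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, config) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  config <- as_sim_config(config)
  df <- data.table::fread(path, sep = "\t")
  need <- c("event_clock", "group_index", "type_index", "count")
  if (!all(need %in% names(df))) {
    stop("trajectory file lacks columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  clocks <- sort(unique(df$event_clock))
  snapshots <- lapply(clocks, function(cl) {
    sub <- df[df$event_clock == cl, ]
    s <- matrix(0L, config$d, config$m)
    s[cbind(sub$type_index + 1L, sub$group_index + 1L)] <- as.integer(sub$count)
    s
  })
  structure(list(config = config, clocks = as.integer(clocks),
                 snapshots = snapshots,
                 event_log = list(immigration = NA_integer_,
                                  replication = NA_integer_,
                                  split = NA_integer_, cull = NA_integer_,
                                  group_removal = NA_integer_,
                                  rng_seed = config$seed)),
            class = "sim_trajectory")
}

#' Write / read a simulation configuration
#'
#' Flat YAML document containing exactly the [sim_config()] fields;
#' unknown keys in a file are an error.
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  config <- as_sim_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, vals)
}

#' Export an interaction table as an edge list
#'
#' Tab-separated table with header `type_i`, `type_j` (0-based), `class`
#' and `orientation` (`i`, `j` or `.`: which side dominates, for dominance
#' edges).
#'
#' @param table Interaction table from [classify_all()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(table, path) {
  table <- as_interaction_table(table)
  orientation <- ifelse(is.na(table$winner), ".",
                        ifelse(table$winner == table$i, "i", "j"))
  out <- data.table::data.table(type_i = table$i - 1L,
                                type_j = table$j - 1L,
                                class = table$class,
                                orientation = orientation)
  data.table::fwrite(out, path, sep = "\t", eol = "\n")
  invisible(path)
}

#' Interaction table as an igraph graph
#'
#' Builds an undirected graph with one node per type and one edge per
#' non-degenerate pair, with the stability class (and dominance winner,
#' where applicable) as edge attributes — convenient for GraphML export
#' via `igraph::write_graph()`.
#'
#' @param table Interaction table from [classify_all()].
#' @param include_degenerate Keep degenerate edges (default `FALSE`).
#' @return An `igraph` object.
#' @export
as_igraph <- function(table, include_degenerate = FALSE) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for graph export", call. = FALSE)
  }
  table <- as_interaction_table(table)
  d <- attr(table, "d")
  edges <- if (include_degenerate) table else table[table$class != "degenerate", ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$i, to = edges$j, class = edges$class,
               winner = ifelse(is.na(edges$winner), -1L, edges$winner)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(d)))
  g
}

#' Write a run manifest
#'
#' Key-value provenance record sufficient to re-derive every output of a
#' run: the resolved configuration, the payoff-matrix checksum, the seed
#' and the produced files.
#'
#' @param config The run's [sim_config()].
#' @param matrix_path Path of the payoff-matrix file used.
#' @param files Character vector of output files produced.
#' @param path Manifest file path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, matrix_path, files, path) {
  config <- as_sim_config(config)
  cfg_lines <- vapply(names(unclass(config)), function(k) {
    paste0("config.", k, ": ", format(config[[k]]))
  }, character(1))
  md5 <- if (file.exists(matrix_path)) unname(tools::md5sum(matrix_path))
         else NA_character_
  lines <- c(paste0("package: mlsim ", as.character(utils::packageVersion("mlsim"))),
             paste0("created: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
             cfg_lines,
             paste0("matrix_file: ", matrix_path),
             paste0("matrix_md5: ", md5),
             paste0("outputs: ", paste(files, collapse = ", ")))
  writeLines(lines, path)
  invisible(path)
}
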