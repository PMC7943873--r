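#' Read a MITAB 2.5 interaction table
#'
#' Parses the tab-separated molecular-interaction format returned by PSICQUIC
#' services. Gene symbols are taken from `uniprotkb:NAME(gene name)` tokens in
#' the alias columns (5--6); when no such token is present the primary
#' identifier (columns 1--2, database prefix stripped) is used instead.
#' Taxa are parsed from `taxid:NNNN` tokens in columns 10--11; a `-` or
#' missing token yields an unknown taxon (`NA`). Lines starting with `#` are
#' treated as comments and skipped.
#'
#' @param path Path to a MITAB file. Data rows must have at least 10
#'   tab-separated columns.
#' @return A tibble of interaction records with columns `interactor_a`,
#'   `interactor_b` (upper-cased gene symbols), `taxon_a`, `taxon_b`
#'   (integer NCBI taxonomy ids, `NA` when unknown) and `source`
#'   (file and line provenance). An empty file yields zero rows.
#' @examples
#' mitab <- system.file("extdata", "example.mitab", package = "netgsea")
#' read_mitab(mitab)
#' @export
read_mitab <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) {
    return(empty_records())
  }
  rows <- strsplit(lines$text, "\t", fixed = TRUE)
  bad <- which(lengths(rows) < 10L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Malformed MITAB row at %s line %d: expected >= 10 tab-separated columns, found %d.",
      path, lines$line[bad[1]], lengths(rows)[bad[1]]
    ))
  }
  sym_a <- vapply(rows, function(r) mitab_symbol(r[[5]], r[[1]]), character(1))
  sym_b <- vapply(rows, function(r) mitab_symbol(r[[6]], r[[2]]), character(1))
  tax_a <- vapply(rows, function(r) mitab_taxon(r[[10]]), integer(1))
  tax_b <- vapply(rows, function(r) mitab_taxon(r[[11]]), integer(1))
  tibble(
    interactor_a = sym_a, interactor_b = sym_b,
    taxon_a = tax_a, taxon_b = tax_b,
    source = sprintf("%s:%d", basename(path), lines$line)
  )
}

# alias field first: any "db:SYMBOL(gene name)" token; fall back to the
# primary id with its "db:" prefix and any "(...)" qualifier stripped
mitab_symbol <- function(alias_field, primary_field) {
  tokens <- strsplit(alias_field, "|", fixed = TRUE)[[1]]
  hit <- grep("\\(gene name\\)\\s*$", tokens, value = TRUE)
  raw <- if (length(hit) > 0L) {
    sub("\\(gene name\\)\\s*$", "", sub("^[^:]*:", "", hit[[1]]))
  } else {
    sub("\\(.*\\)\\s*$", "", sub("^[^:]*:", "", primary_field))
  }
  out <- norm_symbol(raw)
  if (!nzchar(out)) {
    abort("Empty interactor symbol after parsing MITAB identifier fields.")
  }
  out
}

mitab_taxon <- function(field) {
  m <- regmatches(field, regexpr("taxid:-?[0-9]+", field))
  if (length(m) == 0L) {
    return(NA_integer_)
  }
  as.integer(sub("taxid:", "", m, fixed = TRUE))
}

#' Read a two-column edge list or SIF file
#'
#' Lines are split on whitespace. Two tokens give one interaction; three or
#' more tokens are interpreted as SIF (`source relation target [target ...]`)
#' and yield one record per target, ignoring the relation token. Taxa are
#' unknown for this format. Symbols are upper-cased.
#'
#' @param path Path to the edge list / SIF file. `#` comment lines allowed.
#' @return A tibble of interaction records (see [read_mitab()]) with `NA`
#'   taxa.
#' @examples
#' f <- tempfile()
#' writeLines(c("grb2 esr1", "JUN pp FOS"), f)
#' read_edge_list(f)
#' @export
read_edge_list <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) {
    return(empty_records())
  }
  rows <- strsplit(trimws(lines$text), "[ \t]+")
  bad <- which(lengths(rows) < 2L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Malformed edge-list row at %s line %d: a single token is not an edge.",
      path, lines$line[bad[1]]
    ))
  }
  recs <- purrr::map2_dfr(rows, lines$line, function(r, ln) {
    if (length(r) == 2L) {
      a <- r[[1]]
      b <- r[[2]]
    } else {
      a <- rep(r[[1]], length(r) - 2L)
      b <- r[-(1:2)]
    }
    tibble(interactor_a = norm_symbol(a), interactor_b = norm_symbol(b),
           line = ln)
  })
  tibble(
    interactor_a = recs$interactor_a, interactor_b = recs$interactor_b,
    taxon_a = NA_integer_, taxon_b = NA_integer_,
    source = sprintf("%s:%d", basename(path), recs$line)
  )
}

#' Read a GMT gene set collection
#'
#' Each line holds a set name, a description, and one or more member gene
#' symbols, tab-separated. Duplicate members within a line are collapsed;
#' duplicate set names across lines are an error.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_name`, `description`, `genes`
#'   (list-column of upper-cased symbol vectors) and `size`, in file order.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("CELL_CYCLE\tReactome\tCDK1\tCCNB1\tPLK1", f)
#' read_gmt(f)
#' @export
read_gmt <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) {
    return(tibble(set_name = character(), description = character(),
                  genes = list(), size = integer()))
  }
  rows <- strsplit(lines$text, "\t", fixed = TRUE)
  bad <- which(lengths(rows) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Malformed GMT row at %s line %d: need name, description and >= 1 member.",
      path, lines$line[bad[1]]
    ))
  }
  nm <- vapply(rows, `[[`, character(1), 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate gene set name in %s: '%s'.", path, dup[[1]]))
  }
  tibble(
    set_name = nm,
    description = vapply(rows, `[[`, character(1), 2L),
    genes = lapply(rows, function(r) unique(norm_symbol(r[-(1:2)]))),
    size = vapply(rows, function(r) length(unique(norm_symbol(r[-(1:2)]))), integer(1))
  )
}

#' Read a seed (signature) gene list
#'
#' One symbol per line; blank lines and `#` comments are ignored; symbols are
#' upper-cased and de-duplicated, preserving first appearance order.
#'
#' @param path Path to the list file.
#' @return Character vector of seed gene symbols.
#' @export
read_seed_list <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) {
    return(character())
  }
  unique(norm_symbol(sub("#.*$", "", lines$text)))
}

#' Filter interaction records by taxonomy id
#'
#' Keeps records where both interactors carry the requested NCBI taxonomy id,
#' mirroring the species filter used to discard homology-inferred
#' interactions. Records with unknown taxon are dropped in strict mode (the
#' default) and kept when `keep_unknown = TRUE`, which is the sensible mode
#' for edge-list inputs that carry no taxon at all.
#'
#' @param records Interaction record tibble ([read_mitab()] and friends).
#' @param taxid Integer taxonomy id, e.g. `9606` for Homo sapiens.
#' @param keep_unknown Keep records whose taxa are unknown (`NA`)?
#' @return The filtered record tibble (always a subset of the input).
#' @export
filter_taxon <- function(records, taxid, keep_unknown = FALSE) {
  stopifnot(is.numeric(taxid), length(taxid) == 1L)
  known_ok <- !is.na(records$taxon_a) & !is.na(records$taxon_b) &
    records$taxon_a == taxid & records$taxon_b == taxid
  unknown <- is.na(records$taxon_a) & is.na(records$taxon_b)
  keep <- known_ok | (keep_unknown & unknown)
  records[keep, , drop = FALSE]
}

#' Write / read a network as GraphML
#'
#' Thin wrappers over igraph's GraphML support that guarantee the round trip
#' preserves node names, the edge set and the `is_seed` flag.
#'
#' @param network An undirected igraph network with a `name` vertex attribute.
#' @param path Output (or input) file path.
#' @return `write_graphml()` returns `path` invisibly; `read_graphml()`
#'   returns the network.
#' @export
write_graphml <- function(network, path) {
  stopifnot(igraph::is_igraph(network))
  if (is.null(igraph::V(network)$is_seed)) {
    igraph::V(network)$is_seed <- FALSE
  }
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  g <- igraph::as_undirected(g, mode = "collapse")
  if (!is.null(igraph::V(g)$is_seed)) {
    igraph::V(g)$is_seed <- as.logical(igraph::V(g)$is_seed)
  } else {
    igraph::V(g)$is_seed <- FALSE
  }
  g
}

#' Write interaction records as MITAB 2.5
#'
#' Emits a minimal 15-column MITAB table whose alias columns carry
#' `uniprotkb:SYMBOL(gene name)` tokens and whose taxon columns carry
#' `taxid:NNNN(species)` tokens, so the file re-parses through [read_mitab()]
#' and [filter_taxon()] without loss.
#'
#' @param records Interaction record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mitab <- function(records, path) {
  taxf <- function(t) ifelse(is.na(t), "-",
                             sprintf("taxid:%d(%s)", t,
                                     ifelse(t == 9606L, "human", "species")))
  rows <- sprintf(
    "uniprotkb:%s\tuniprotkb:%s\t-\t-\tuniprotkb:%s(gene name)\tuniprotkb:%s(gene name)\tpsi-mi:\"MI:0000\"\t-\t-\t%s\t%s\tpsi-mi:\"MI:0915\"\tpsi-mi:\"MI:0000\"\t-\t-",
    records$interactor_a, records$interactor_b,
    records$interactor_a, records$interactor_b,
    taxf(records$taxon_a), taxf(records$taxon_b)
  )
  writeLines(rows, path)
  invisible(path)
}

#' Write a gene set collection as GMT
#'
#' @param collection Gene set tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  rows <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$set_name[[i]], collection$description[[i]],
            collection$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Write a seed gene list
#'
#' @param seeds Character vector of symbols.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seed_list <- function(seeds, path) {
  writeLines(norm_symbol(seeds), path)
  invisible(path)
}

#' Write named result tables as TSV files
#'
#' @param tables Named list of data frames; each is written to
#'   `<directory>/<name>.tsv` with a header row.
#' @param directory Output directory, created if missing.
#' @return Character vector of the written paths, invisibly.
#' @export
write_tsv_tables <- function(tables, directory) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(directory, paste0(nm, ".tsv"))
    readr::write_tsv(flatten_list_cols(tables[[nm]]), p, progress = FALSE)
    p
  }, character(1))
  invisible(paths)
}

# list-columns (e.g. leading_edge) are serialized semicolon-joined
flatten_list_cols <- function(df) {
  is_list <- vapply(df, is.list, logical(1))
  for (col in names(df)[is_list]) {
    df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ";")
  }
  df
}

# shared line reader: keeps original line numbers, drops blanks and comments
read_data_lines <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path))
  }
  raw <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(raw)) & !startsWith(trimws(raw), "#"))
  list(text = raw[keep], line = keep)
}

empty_records <- function() {
  tibble(interactor_a = character(), interactor_b = character(),
         taxon_a = integer(), taxon_b = integer(), source = character())
}
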