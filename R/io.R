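# Readers and writers for the plain-text formats the tool touches: OBO 1.2
# ontologies, GAF 2.x annotation files, pfam2go-style mappings, whitespace
# edge lists and ragged module TSVs. All readers tolerate CRLF endings.

read_text_lines <- function(path) {
  check_file_exists(path)
  gsub("\r$", "", readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' Read an OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas, ingesting `is_a:` and `relationship: part_of`
#' lines (the two relation kinds are treated identically) and skipping
#' obsolete terms. Terms are grouped by `namespace:`; each namespace must
#' form an acyclic graph funnelling into a single root. Relations that point
#' outside a term's namespace or to unknown/obsolete terms are dropped with
#' a warning.
#'
#' @param path Path to an OBO file.
#' @return A single [ontology_graph()] when the file holds one namespace,
#'   otherwise a named list of them.
#' @export
read_obo <- function(path) {
  lines <- read_text_lines(path)
  starts <- grep("^\\[", lines)
  if (length(starts) == 0L) {
    abort("no stanzas found in OBO input.", class = "funcoh_error_parse")
  }
  bounds <- c(starts, length(lines) + 1L)
  terms <- list()
  for (s in seq_along(starts)) {
    block <- lines[starts[s]:(bounds[s + 1L] - 1L)]
    if (!identical(block[1L], "[Term]")) next
    field <- function(key) {
      v <- sub(paste0("^", key, ":\\s*"), "",
               grep(paste0("^", key, ":"), block, value = TRUE))
      sub("\\s*!.*$", "", v)  # strip trailing comments
    }
    id <- field("id")
    if (length(id) != 1L || !nzchar(id)) next
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    rel <- field("relationship")
    part_of <- sub("^part_of\\s+", "",
                   grep("^part_of\\s", rel, value = TRUE))
    ns <- field("namespace")
    terms[[id]] <- list(
      id = id,
      namespace = if (length(ns) == 1L) ns else "default",
      parents = unique(c(field("is_a"), part_of))
    )
  }
  if (length(terms) == 0L) {
    abort("OBO input contains no usable [Term] stanza.",
          class = "funcoh_error_parse")
  }
  ns_of <- vapply(terms, `[[`, character(1), "namespace")
  out <- lapply(unique(ns_of), function(ns) {
    ids <- names(terms)[ns_of == ns]
    rel <- purrr::map_dfr(terms[ids], function(t) {
      p <- intersect(t$parents, ids)
      if (length(p) < length(t$parents)) {
        warn(sprintf("term %s: dropped %d relation(s) to unknown or foreign terms.",
                     t$id, length(t$parents) - length(p)))
      }
      if (length(p) == 0L) return(NULL)
      tibble::tibble(term = t$id, parent = p)
    })
    if (nrow(rel) == 0L) {
      abort(sprintf("namespace '%s' has no relations; cannot locate a root.",
                    ns),
            class = "funcoh_error_structure")
    }
    ontology_graph(rel)
  })
  names(out) <- unique(ns_of)
  if (length(out) == 1L) out[[1L]] else out
}

#' Write an ontology as OBO
#'
#' @param ontology An [ontology_graph()] object.
#' @param path Output path.
#' @param namespace Namespace written into each stanza.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path, namespace = "biological_process") {
  stopifnot(inherits(ontology, "ontology_dag"))
  rel <- tidy.ontology_dag(ontology)
  parents <- split(rel$parent, rel$term)
  stanzas <- vapply(ontology$terms, function(t) {
    p <- parents[[t]] %||% character(0)
    paste(c("[Term]",
            paste0("id: ", t),
            paste0("name: ", t),
            paste0("namespace: ", namespace),
            if (length(p) > 0) paste0("is_a: ", p),
            ""),
          collapse = "\n")
  }, character(1))
  writeLines(c("format-version: 1.2", "", stanzas), path)
  invisible(path)
}

#' Read a GAF 2.x annotation file
#'
#' Builds an [annotation_corpus()] from a tab-separated Gene Association
#' File. Comment lines (starting with `!`) are skipped, rows with a `NOT`
#' qualifier are dropped, and rows can be filtered by aspect
#' (`P`/`F`/`C`) and by evidence code. Annotations to terms absent from the
#' ontology are dropped with a warning; per-molecule term sets are reduced
#' to their most specific members.
#'
#' @param path Path to a GAF file.
#' @param ontology The [ontology_graph()] the annotations refer to.
#' @param aspect Optional aspect filter (column 9), e.g. `"P"`.
#' @param evidence Optional character vector of evidence codes to keep
#'   (column 7); default keeps everything.
#' @param lenient If `TRUE`, lines with fewer than 15 columns are skipped
#'   with a warning instead of raising an error.
#' @return An [annotation_corpus()].
#' @export
read_gaf <- function(path, ontology, aspect = NULL, evidence = NULL,
                     lenient = FALSE) {
  stopifnot(inherits(ontology, "ontology_dag"))
  lines <- read_text_lines(path)
  keep <- !grepl("^!", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    abort("GAF input contains no annotation rows.",
          class = "funcoh_error_parse")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 15L
  if (any(bad)) {
    if (lenient) {
      warn(sprintf("skipped %d malformed GAF line(s).", sum(bad)))
      fields <- fields[!bad]
    } else {
      abort(sprintf("GAF line %d: expected at least 15 columns, found %d.",
                    lineno[which(bad)[1L]], lengths(fields)[which(bad)[1L]]),
            class = "funcoh_error_parse")
    }
  }
  rec <- tibble::tibble(
    molecule  = vapply(fields, `[[`, character(1), 2L),
    qualifier = vapply(fields, `[[`, character(1), 4L),
    term      = vapply(fields, `[[`, character(1), 5L),
    evidence  = vapply(fields, `[[`, character(1), 7L),
    aspect    = vapply(fields, `[[`, character(1), 9L)
  )
  rec <- rec[!grepl("(^|\\|)NOT($|\\|)", rec$qualifier), , drop = FALSE]
  if (!is.null(aspect)) rec <- rec[rec$aspect %in% aspect, , drop = FALSE]
  if (!is.null(evidence)) rec <- rec[rec$evidence %in% evidence, , drop = FALSE]
  if (nrow(rec) == 0L) {
    abort("no GAF rows left after filtering.", class = "funcoh_error_parse")
  }
  annotation_corpus(ontology, rec[, c("molecule", "term")])
}

#' Write a corpus as GAF 2.2
#'
#' Emits one row per stored (most specific) annotation, with placeholder
#' metadata columns, suitable for round-tripping through [read_gaf()].
#'
#' @param corpus An [annotation_corpus()].
#' @param path Output path.
#' @param aspect Aspect code written in column 9.
#' @param db Database label written in column 1.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(corpus, path, aspect = "P", db = "FC") {
  stopifnot(inherits(corpus, "annotation_corpus"))
  ann <- tidy.annotation_corpus(corpus)
  rows <- sprintf(
    "%s\t%s\t%s\t\t%s\tFC:0000001\tIEA\t\t%s\t\t\tprotein\ttaxon:0\t20090309\t%s\t\t",
    db, ann$molecule, ann$molecule, ann$term, aspect, db)
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}

#' Read a pfam2go-style term mapping
#'
#' Accepts either the external2go line format
#' `Pfam:PF00001 name > GO:label ; GO:0000001` (the term is taken after the
#' final semicolon, the molecule is the first whitespace token) or a plain
#' two-column TSV of molecule and term. Comment lines (`!`) are skipped and
#' duplicate pairs collapse to a single association; mappings to unknown
#' terms are dropped with a warning.
#'
#' @param path Path to the mapping file.
#' @param ontology The [ontology_graph()] the terms refer to.
#' @return An [annotation_corpus()].
#' @export
read_term_mapping <- function(path, ontology) {
  stopifnot(inherits(ontology, "ontology_dag"))
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    abort("mapping input contains no records.", class = "funcoh_error_parse")
  }
  arrow <- grepl(">", lines, fixed = TRUE)
  mol <- character(length(lines))
  term <- character(length(lines))
  mol[arrow] <- vapply(strsplit(lines[arrow], "\\s+"), `[[`, character(1), 1L)
  term[arrow] <- trimws(sub(".*;", "", lines[arrow]))
  if (any(!arrow)) {
    cols <- strsplit(lines[!arrow], "[\t ]+")
    if (any(lengths(cols) < 2L)) {
      abort("two-column mapping line with fewer than two fields.",
            class = "funcoh_error_parse")
    }
    mol[!arrow] <- vapply(cols, `[[`, character(1), 1L)
    term[!arrow] <- vapply(cols, `[[`, character(1), 2L)
  }
  annotation_corpus(ontology, tibble::tibble(molecule = mol, term = term))
}

#' Read an undirected edge list
#'
#' Whitespace- or tab-separated lines `nodeA nodeB [weight]`; duplicate
#' edges are merged by weight sum, self-loops dropped.
#'
#' @param path Path to the edge list.
#' @return An [interaction_graph()].
#' @export
read_edge_list <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    abort("edge list is empty.", class = "funcoh_error_parse")
  }
  cols <- strsplit(trimws(lines), "[\t ]+")
  if (any(lengths(cols) < 2L)) {
    abort("edge list line with fewer than two fields.",
          class = "funcoh_error_parse")
  }
  interaction_graph(tibble::tibble(
    from = vapply(cols, `[[`, character(1), 1L),
    to = vapply(cols, `[[`, character(1), 2L),
    weight = vapply(cols, function(x)
      if (length(x) >= 3L) as.numeric(x[3L]) else 1, numeric(1))
  ))
}

#' Write an interaction graph as an edge list
#'
#' @param graph An [interaction_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  e <- tidy.interaction_graph(graph)
  e <- dplyr::arrange(e, .data$from, .data$to)
  writeLines(sprintf("%s\t%s\t%g", e$from, e$to, e$weight), path)
  invisible(path)
}

#' Read a module list
#'
#' One module per line: a module identifier followed by its member molecule
#' identifiers, tab-separated.
#'
#' @param path Path to the module TSV.
#' @return A tibble with columns `module` and `molecule`.
#' @export
read_modules <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    abort("module file is empty.", class = "funcoh_error_parse")
  }
  cols <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(cols) < 2L)) {
    abort("module line with no members.", class = "funcoh_error_parse")
  }
  tibble::tibble(
    module = rep(vapply(cols, `[[`, character(1), 1L), lengths(cols) - 1L),
    molecule = unlist(lapply(cols, `[`, -1L), use.names = FALSE)
  )
}

#' Write a module list
#'
#' @param modules A data frame with columns `module` and `molecule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path) {
  members <- split(as.character(modules$molecule),
                   as.character(modules$module))
  ids <- sort(names(members))
  writeLines(vapply(ids, function(id)
    paste(c(id, members[[id]]), collapse = "\t"), character(1)), path)
  invisible(path)
}
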