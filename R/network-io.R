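#' Read and write networks as JSON
#'
#' A network is stored as a single self-contained JSON document with five
#' top-level keys: `meta`, `entities`, `reactions`, `regulations` and
#' `transcription_units` (the schema ships in
#' `system.file("schema", "network-schema.json", package = "metregr")`).
#' Writing is byte-stable: records are emitted in table order with a fixed key
#' order, so `write_network()` of an unchanged network reproduces the file
#' exactly. `read_network()` validates the result and reports dangling
#' references, duplicate ids and malformed records with the offending id.
#'
#' @param path File path.
#' @param net A `metreg_network`.
#' @param validate Validate after reading (default `TRUE`).
#' @return `read_network()` returns a `metreg_network`; `write_network()`
#'   returns `path` invisibly.
#' @export
read_network <- function(path, validate = TRUE) {
  if (!file.exists(path))
    rlang::abort(glue::glue("network file not found: {path}"))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) rlang::abort(
      glue::glue("cannot parse {path}: {conditionMessage(e)}"))
  )
  net <- network()
  net$meta$schema_version <- doc$meta$schema_version %||% "1.0"
  chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  for (e in doc$entities %||% list()) {
    comp <- NULL
    if (!is.null(e$components) && length(e$components)) {
      comp <- unlist(e$components)
    }
    net <- add_entity_row(
      net, as.character(e$id), as.character(e$kind),
      chr1(e$name) %|na|% as.character(e$id),
      if (is.null(e$ubiquitous)) NA else as.logical(e$ubiquitous),
      chr1(e$base_entity), chr1(e$gene), comp
    )
  }
  lchr <- function(x) as.character(unlist(x %||% list()))
  for (r in doc$reactions %||% list()) {
    net <- add_reaction(
      net, as.character(r$id), lchr(r$reactants), lchr(r$products),
      chr1(r$direction) %|na|% "left-to-right", lchr(r$enzymes),
      isTRUE(r$is_transport), lchr(r$transported), isTRUE(r$is_protein_binding)
    )
  }
  for (g in doc$regulations %||% list()) {
    net <- add_regulation(net, as.character(g$id), as.character(g$regulator),
                          as.character(g$regulatee), as.character(g$mode),
                          chr1(g$sign) %|na|% "+")
  }
  for (u in doc$transcription_units %||% list()) {
    net <- add_transcription_unit(net, as.character(u$id), lchr(u$genes))
  }
  if (validate) validate_network(net)
  net
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

#' @rdname read_network
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "metreg_network"))
  drop_na <- function(x) x[!vapply(x, function(v)
    is.null(v) || (length(v) == 1 && is.na(v)), logical(1))]
  ents <- purrr::pmap(net$entities, function(id, kind, name, ubiquitous,
                                             base_entity, gene, components) {
    drop_na(list(
      id = id, kind = kind, name = name, ubiquitous = ubiquitous,
      base_entity = base_entity, gene = gene,
      components = if (length(components)) as.list(components) else NULL
    ))
  })
  rxns <- purrr::pmap(net$reactions, function(id, direction, is_transport,
                                              is_protein_binding, reactants,
                                              products, enzymes, transported) {
    drop_na(list(
      id = id, direction = direction, reactants = as.list(reactants),
      products = as.list(products),
      enzymes = if (length(enzymes)) as.list(enzymes) else NULL,
      is_transport = if (is_transport) TRUE else NULL,
      transported = if (length(transported)) as.list(transported) else NULL,
      is_protein_binding = if (is_protein_binding) TRUE else NULL
    ))
  })
  regs <- purrr::pmap(net$regulations, function(id, regulator, regulatee,
                                                mode, sign) {
    list(id = id, regulator = regulator, regulatee = regulatee,
         mode = mode, sign = sign)
  })
  tus <- purrr::pmap(net$transcription_units, function(id, genes) {
    list(id = id, genes = as.list(genes))
  })
  doc <- list(meta = list(schema_version = net$meta$schema_version),
              entities = ents, reactions = rxns, regulations = regs,
              transcription_units = tus)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA,
                           null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, useBytes = TRUE)
  invisible(path)
}

#' Dump a network as TSV tables
#'
#' Writes one UTF-8, tab-delimited file per record type
#' (`entities.tsv`, `reactions.tsv`, `regulations.tsv`,
#' `transcription_units.tsv`) for inspection with command-line tools or
#' spreadsheets. List-valued fields are `;`-joined; complex components are
#' rendered `id:count`.
#'
#' @param net A `metreg_network`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_network_tsv <- function(net, dir) {
  stopifnot(inherits(net, "metreg_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  joinc <- function(col) purrr::map_chr(col, ~ paste(.x, collapse = ";"))
  ent <- net$entities |>
    dplyr::mutate(components = purrr::map_chr(
      .data$components,
      ~ paste(sprintf("%s:%g", names(.x), .x), collapse = ";")))
  readr::write_tsv(ent, file.path(dir, "entities.tsv"))
  rx <- net$reactions |>
    dplyr::mutate(dplyr::across(c("reactants", "products", "enzymes",
                                  "transported"), joinc))
  readr::write_tsv(rx, file.path(dir, "reactions.tsv"))
  readr::write_tsv(net$regulations, file.path(dir, "regulations.tsv"))
  tu <- net$transcription_units |> dplyr::mutate(genes = joinc(.data$genes))
  readr::write_tsv(tu, file.path(dir, "transcription_units.tsv"))
  invisible(dir)
}
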