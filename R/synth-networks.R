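#' Parameters for the synthetic-network generator
#'
#' Defaults describe a small but structurally complete network: a dozen
#' metabolites with heavy-tailed reaction participation (so common-hub
#' compounds exist and specificity weighting is exercised), ten reactions
#' with occasional reversibility and transport, six enzymes, three
#' transcription factors with signed regulation, and a sprinkling of
#' translational, sigma-factor, modulation and cofactor records, complexes,
#' modified forms and transcription units. Identical seed and parameters
#' always produce an identical network.
#'
#' @param n_metabolites,n_reactions,n_enzymes,n_tfs,n_tus Record counts.
#' @param p_reversible,p_transport,p_regulation,p_modulation,p_cofactor
#'   Probabilities in `[0, 1]`.
#' @param ubiquitous_fraction Fraction of metabolites flagged ubiquitous.
#' @param seed Integer seed.
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_metabolites = 12, n_reactions = 10, n_enzymes = 6,
                         n_tfs = 3, n_tus = 2, p_reversible = 0.2,
                         p_transport = 0.1, p_regulation = 0.3,
                         p_modulation = 0.15, p_cofactor = 0.1,
                         ubiquitous_fraction = 0.15, seed = 1) {
  p <- list(n_metabolites = n_metabolites, n_reactions = n_reactions,
            n_enzymes = n_enzymes, n_tfs = n_tfs, n_tus = n_tus,
            p_reversible = p_reversible, p_transport = p_transport,
            p_regulation = p_regulation, p_modulation = p_modulation,
            p_cofactor = p_cofactor,
            ubiquitous_fraction = ubiquitous_fraction, seed = seed)
  counts <- unlist(p[1:5])
  probs <- unlist(p[6:11])
  if (any(counts < 0)) rlang::abort("counts must be non-negative")
  if (any(probs < 0 | probs > 1)) rlang::abort("probabilities must be in [0,1]")
  if (n_reactions > 0 && n_metabolites < 2)
    rlang::abort("reactions need at least two metabolites")
  structure(p, class = "synth_params")
}

#' Generate a random synthetic network
#'
#' Produces a validated network exercising every influence-edge type that
#' has probability mass under the parameters: weighted random reactions
#' (metabolite participation drawn with heavy-tailed weights), enzymes,
#' transport and protein-binding reactions, signed transcriptional
#' regulation plus translational and sigma-factor records, enzyme modulation
#' and cofactors, homo- and heteromultimeric complexes, a modified form, and
#' transcription units. Generation is fully seed-deterministic and does not
#' disturb the caller's RNG state.
#'
#' @param params A `synth_params` list.
#' @return A valid `metreg_network`.
#' @export
generate_network <- function(params = synth_params()) {
  if (!inherits(params, "synth_params")) params <- do.call(synth_params, params)
  withr::with_seed(params$seed, generate_network_impl(params))
}

generate_network_impl <- function(p) {
  net <- network()
  mets <- sprintf("M%02d", seq_len(p$n_metabolites))
  n_ubi <- round(p$ubiquitous_fraction * p$n_metabolites)
  ubi <- if (n_ubi > 0) sample(mets, n_ubi) else character()
  for (m in mets) net <- add_metabolite(net, m, ubiquitous = m %in% ubi)
  enz <- sprintf("E%02d", seq_len(p$n_enzymes))
  net <- purrr::reduce(enz, \(n, e) add_gene_product(n, e), .init = net)
  tfs <- sprintf("T%02d", seq_len(p$n_tfs))
  net <- purrr::reduce(tfs, \(n, t) add_gene_product(n, t), .init = net)
  prot <- function(x) paste0(x, "_p")

  # heavy-tailed participation weights over metabolites
  w <- 1 / seq_along(mets)^1.2
  pick_mets <- function(k, exclude = character()) {
    pool <- setdiff(mets, exclude)
    if (!length(pool)) return(character())
    pool[sample.int(length(pool), min(k, length(pool)),
                    prob = w[match(pool, mets)])]
  }

  for (i in seq_len(p$n_reactions)) {
    re <- pick_mets(sample(1:2, 1))
    pr <- pick_mets(sample(1:2, 1), exclude = re)
    if (!length(re) || !length(pr)) next
    dir <- if (stats::runif(1) < p$p_reversible) "reversible" else "left-to-right"
    e <- if (p$n_enzymes > 0 && stats::runif(1) < 0.9) sample(prot(enz), 1)
         else character()
    transport <- stats::runif(1) < p$p_transport
    net <- add_reaction(net, sprintf("R%02d", i), re, pr, dir, e,
                        is_transport = transport,
                        transported = if (transport) pr[1] else character())
  }

  # structural extras guaranteeing coverage of the remaining edge types
  if (p$n_enzymes >= 2) {
    net <- net |>
      add_complex("CPXH", stats::setNames(2, prot(enz[1]))) |>
      add_complex("CPXAB", stats::setNames(c(1, 1), prot(enz[1:2])))
  }
  if (p$n_tfs >= 1 && p$n_metabolites >= 2) {
    net <- net |>
      add_modified_form(paste0(prot(tfs[1]), "_P"), prot(tfs[1])) |>
      add_reaction("RBIND", c(prot(tfs[1]), mets[1]),
                   paste0(prot(tfs[1]), "_P"), enzymes = character(),
                   is_protein_binding = TRUE)
  }

  genes <- c(enz, tfs)
  ri <- 0
  reg <- function(n, regulator, regulatee, mode, sign = "+") {
    ri <<- ri + 1
    add_regulation(n, sprintf("REG%03d", ri), regulator, regulatee, mode, sign)
  }
  for (t in tfs) {
    for (g in genes) {
      if (g == t) next
      if (stats::runif(1) < p$p_regulation) {
        net <- reg(net, prot(t), g, "transcriptional",
                   if (stats::runif(1) < 0.5) "+" else "-")
      }
    }
  }
  if (p$n_tfs >= 2 && p$n_enzymes >= 2) {
    net <- reg(net, prot(tfs[2]), enz[1], "translational", "-")
    net <- reg(net, prot(tfs[p$n_tfs]), enz[2], "sigma-factor")
  }
  catalysts <- unique(unlist(net$reactions$enzymes))
  if (length(catalysts)) {
    alt <- TRUE
    for (m in mets) {
      if (stats::runif(1) < p$p_modulation) {
        net <- reg(net, m, sample(catalysts, 1), "enzyme-modulation",
                   if (alt) "+" else "-")
        alt <- !alt
      }
      if (stats::runif(1) < p$p_cofactor) {
        net <- reg(net, m, sample(catalysts, 1), "cofactor")
      }
    }
  }
  if (length(genes) >= 2) {
    for (i in seq_len(p$n_tus)) {
      members <- sample(genes, min(length(genes), sample(2:3, 1)))
      net <- add_transcription_unit(net, sprintf("TU%02d", i), members)
    }
  }
  validate_network(net)
  net
}

#' A small fixed fixture network
#'
#' A hand-built network inspired by a minimal worked example: enzyme E1
#' catalyses the conversion of metabolite M0 to M1, transcription factor TF0
#' represses transcription factor TF1 and activates expression of enzyme E5.
#' Those three relations are the documented core; the remaining reactions,
#' enzymes and regulations complete the fixture to five reactions and three
#' transcription factors and are fixture inventions, as recorded relation by
#' relation in the attached `manifest` attribute (`provenance` column:
#' `"documented"` or `"invented"`).
#'
#' @return A valid `metreg_network` with a `manifest` attribute.
#' @export
toy_network <- function() {
  net <- network()
  for (m in paste0("M", 0:6)) net <- add_metabolite(net, m)
  for (e in paste0("E", 1:5)) net <- add_gene_product(net, e)
  for (t in paste0("TF", 0:2)) net <- add_gene_product(net, t)
  net <- net |>
    add_reaction("R1", "M0", "M1", enzymes = "E1_p") |>
    add_reaction("R2", "M1", "M2", enzymes = "E2_p") |>
    add_reaction("R3", "M2", "M3", enzymes = "E3_p") |>
    add_reaction("R4", "M3", "M6", enzymes = "E4_p") |>
    add_reaction("R5", "M4", "M5", enzymes = "E5_p") |>
    add_regulation("G1", "TF0_p", "TF1", "transcriptional", "-") |>
    add_regulation("G2", "TF0_p", "E5", "transcriptional", "+") |>
    add_regulation("G3", "TF1_p", "E1", "transcriptional", "+") |>
    add_regulation("G4", "TF2_p", "E2", "transcriptional", "+") |>
    add_regulation("G5", "TF0_p", "TF2", "transcriptional", "+") |>
    add_transcription_unit("TU1", c("E2", "E3"))
  validate_network(net)
  attr(net, "manifest") <- tibble::tibble(
    relation = c("R1: E1 catalyses M0 -> M1",
                 "G1: TF0 represses TF1",
                 "G2: TF0 activates E5",
                 "R2: E2 catalyses M1 -> M2", "R3: E3 catalyses M2 -> M3",
                 "R4: E4 catalyses M3 -> M6", "R5: E5 catalyses M4 -> M5",
                 "G3: TF1 activates E1", "G4: TF2 activates E2",
                 "G5: TF0 activates TF2", "TU1: E2,E3 co-transcribed"),
    provenance = c("documented", "documented", "documented",
                   rep("invented", 8)))
  net
}

planted_x_class <- list(
  "reactant-of-producing" = c("met", "gp"),
  "reactant-of-consuming" = c("met", "gp"),
  "product-of-consuming" = c("met", "gp"),
  "enzyme-of-producing" = c("met", "gp"),
  "enzyme-of-consuming" = c("met", "gp"),
  "transporter" = "met",
  "enzyme-activator" = "gp", "enzyme-inhibitor" = "gp", "cofactor" = "gp",
  "transcriptional-regulator" = c("gp", "cx"),
  "translational-regulator" = c("gp", "cx"),
  "sigma-factor" = c("gp", "cx"),
  "complex-component" = "cx")

planted_i_class <- list(
  "reactant-of-producing" = c("met", "gp"),
  "reactant-of-consuming" = c("met", "gp"),
  "product-of-consuming" = c("met", "gp"),
  "enzyme-of-producing" = c("gp", "cx"),
  "enzyme-of-consuming" = c("gp", "cx"),
  "transporter" = c("gp", "cx"),
  "enzyme-activator" = c("met", "gp"),
  "enzyme-inhibitor" = c("met", "gp"),
  "cofactor" = c("met", "gp"),
  "transcriptional-regulator" = c("gp", "cx"),
  "translational-regulator" = c("gp", "cx"),
  "sigma-factor" = c("gp", "cx"),
  "complex-component" = c("gp", "cx"))

#' Generate a network with one planted condition-to-effect path
#'
#' Builds a network containing a single ground-truth path of the requested
#' influence-edge types from an effect entity `N0` to a condition entity
#' `N<k>`, plus `decoys` random distractor records (extra reactions,
#' regulators and modulators hanging off the path), and returns the network
#' together with the expected path skeleton. Decoys never touch the
#' condition entity, so the planted path remains a genuine route. Node kinds
#' are negotiated between consecutive edge types; incompatible combinations
#' (or transcription-unit links, which are undirected-only dead ends) raise
#' an unrealizable-specification error.
#'
#' @param path_spec Character vector of influence types (effect side first).
#' @param decoys Number of decoy records.
#' @param seed Integer seed.
#' @return A list with `net`, `effect`, `condition`, and `expected` (tibble
#'   `from`, `to`, `type`).
#' @export
planted_path_network <- function(path_spec, decoys = 20, seed = 1) {
  if (!length(path_spec)) rlang::abort("path_spec must be non-empty")
  bad <- setdiff(path_spec, influence_types())
  if (length(bad)) rlang::abort(glue::glue("unknown influence type \"{bad[1]}\""))
  if ("transcription-unit" %in% path_spec)
    rlang::abort(paste("unrealizable path specification:",
                       "transcription-unit links are undirected-only dead ends"))
  k <- length(path_spec)
  classes <- character(k + 1)
  pref <- function(opts) {
    for (cl in c("met", "gp", "cx")) if (cl %in% opts) return(cl)
    NULL
  }
  classes[1] <- pref(planted_x_class[[path_spec[1]]])
  for (j in seq_len(k)) {
    opts <- planted_i_class[[path_spec[j]]]
    if (j < k) opts <- intersect(opts, planted_x_class[[path_spec[j + 1]]])
    if (j == k) opts <- intersect(opts, c("gp", "met", "cx"))
    cl <- pref(opts)
    if (is.null(cl))
      rlang::abort(glue::glue(
        "unrealizable path specification at step {j} ({path_spec[j]})"))
    classes[j + 1] <- cl
  }
  withr::with_seed(seed, planted_path_impl(path_spec, classes, decoys))
}

planted_path_impl <- function(path_spec, classes, decoys) {
  k <- length(path_spec)
  net <- network()
  ids <- paste0("N", 0:k)
  prot <- function(x) paste0(x, "_p")
  aux <- 0
  new_aux <- function(prefix) {
    aux <<- aux + 1
    paste0(prefix, aux)
  }
  # create path nodes
  for (j in seq_along(ids)) {
    id <- ids[j]
    net <- switch(classes[j],
      met = add_metabolite(net, id),
      gp = add_gene_product(net, id),
      cx = net)  # complexes are created by their complex-component edge
  }
  ri <- 0
  rx <- function(n, re, pr, ...) {
    ri <<- ri + 1
    add_reaction(n, sprintf("PR%02d", ri), re, pr, ...)
  }
  gi <- 0
  rg <- function(n, regulator, regulatee, mode, sign = "+") {
    gi <<- gi + 1
    add_regulation(n, sprintf("PG%02d", gi), regulator, regulatee, mode, sign)
  }
  as_substrate <- function(j) if (classes[j + 1] == "met") ids[j + 1]
    else prot(ids[j + 1])
  as_catalyst <- function(j) if (classes[j + 1] == "cx") ids[j + 1]
    else prot(ids[j + 1])
  ensure_enzyme <- function(n, j) {
    # modulated/cofactored entities must catalyse something
    s <- new_aux("S"); w <- new_aux("W")
    n |> add_metabolite(s) |> add_metabolite(w) |>
      rx(s, w, enzymes = as_catalyst(j))
  }
  for (j in seq_len(k)) {
    x <- ids[j]; i <- ids[j + 1]
    xs <- as_substrate(j - 1); is <- as_substrate(j)
    net <- switch(path_spec[j],
      "reactant-of-producing" = rx(net, is, xs),
      "reactant-of-consuming" = {
        w <- new_aux("W")
        net |> add_metabolite(w) |> rx(c(xs, is), w)
      },
      "product-of-consuming" = rx(net, xs, is),
      "enzyme-of-producing" = {
        s <- new_aux("S")
        net |> add_metabolite(s) |> rx(s, xs, enzymes = as_catalyst(j))
      },
      "enzyme-of-consuming" = {
        w <- new_aux("W")
        net |> add_metabolite(w) |> rx(xs, w, enzymes = as_catalyst(j))
      },
      "transporter" = {
        s <- new_aux("S")
        net |> add_metabolite(s) |>
          rx(s, xs, enzymes = as_catalyst(j), is_transport = TRUE,
             transported = xs)
      },
      "enzyme-activator" = rg(ensure_enzyme(net, j - 1), is, prot(x),
                              "enzyme-modulation", "+"),
      "enzyme-inhibitor" = rg(ensure_enzyme(net, j - 1), is, prot(x),
                              "enzyme-modulation", "-"),
      "cofactor" = rg(ensure_enzyme(net, j - 1), is, prot(x), "cofactor"),
      "transcriptional-regulator" = rg(net, prot(i), x, "transcriptional",
                                       "+"),
      "translational-regulator" = rg(net, prot(i), x, "translational", "+"),
      "sigma-factor" = rg(net, prot(i), x, "sigma-factor"),
      "complex-component" = {
        f <- new_aux("F")
        net |> add_protein(prot(f)) |>
          add_complex(x, stats::setNames(c(1, 1), c(prot(i), prot(f))))
      })
  }

  # decoy structure: distractors hanging off the path, never touching the
  # condition entity
  path_mets <- ids[classes == "met" & seq_along(ids) <= k]
  path_genes <- ids[classes == "gp" & seq_along(ids) <= k]
  for (d in seq_len(decoys)) {
    kindd <- sample(c("producer", "consumer", "tf", "modulator"), 1)
    if (kindd %in% c("producer", "consumer") && length(path_mets)) {
      m <- sample(path_mets, 1)
      dm <- new_aux("D")
      net <- add_metabolite(net, dm)
      net <- if (kindd == "producer") rx(net, dm, m) else {
        w <- new_aux("W")
        net |> add_metabolite(w) |> rx(c(m, dm), w)
      }
    } else if (kindd == "tf" && length(path_genes)) {
      dt <- new_aux("DT")
      net <- net |> add_gene_product(dt) |>
        rg(prot(dt), sample(path_genes, 1), "transcriptional",
           if (stats::runif(1) < 0.5) "+" else "-")
    } else if (kindd == "modulator") {
      catalysts <- unique(unlist(net$reactions$enzymes))
      catalysts <- setdiff(catalysts, c(prot(ids[k + 1]), ids[k + 1]))
      if (length(catalysts)) {
        dm <- new_aux("DM")
        net <- net |> add_metabolite(dm) |>
          rg(dm, sample(catalysts, 1), "enzyme-modulation", "-")
      }
    }
  }
  validate_network(net)
  lmap <- logical_node_map(net)
  to_l <- function(e) unname(lmap[[e]])
  expected <- tibble::tibble(
    from = vapply(ids[seq_len(k)], to_l, character(1)),
    to = vapply(ids[1 + seq_len(k)], to_l, character(1)),
    type = path_spec)
  list(net = net, effect = to_l(ids[1]), condition = to_l(ids[k + 1]),
       expected = expected)
}
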