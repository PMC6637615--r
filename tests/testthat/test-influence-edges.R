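test_that("an isolated metabolite has no influencers", {
  net <- network() |> add_metabolite("M") |> add_metabolite("A") |>
    add_metabolite("B") |> add_reaction("R1", "A", "B")
  expect_equal(nrow(influencers_of("M", net)), 0)
})

test_that("a produced metabolite sees its enzyme and co-reactants", {
  net <- network() |> add_metabolite("M") |> add_metabolite("A") |>
    add_gene_product("E1") |>
    add_reaction("R1", "A", "M", enzymes = "E1_p")
  e <- influencers_of("M", net)
  expect_setequal(paste(e$type, e$to),
                  c("reactant-of-producing A", "enzyme-of-producing E1"))
  # the consumed-side reading for the reactant
  ea <- influencers_of("A", net)
  expect_setequal(paste(ea$type, ea$to),
                  c("product-of-consuming M", "enzyme-of-consuming E1"))
})

test_that("transcription-unit links appear only in undirected mode", {
  net <- network() |> add_gene_product("g") |>
    add_transcription_unit("tu1", "g")
  expect_false("transcription-unit" %in% influencers_of("g", net,
                                                        "directed")$type)
  e <- influencers_of("g", net, "undirected")
  expect_equal(e$to[e$type == "transcription-unit"], "tu1")
})

test_that("ubiquitous compounds generate no substrate edges in either role", {
  net <- network() |> add_metabolite("M") |> add_metabolite("water") |>
    add_gene_product("E") |>
    add_reaction("R1", c("M", "water"), "P", enzymes = "E_p") |>
    add_metabolite("P")
  e <- influencers_of("water", net)
  expect_equal(nrow(e), 0)
  em <- influencers_of("M", net)
  expect_false("water" %in% em$to)
})

test_that("protein-binding reactions are skipped for small molecules only", {
  net <- network() |> add_metabolite("L") |> add_gene_product("E") |>
    add_modified_form("E_b", "E_p") |>
    add_reaction("RB", c("L", "E_p"), "E_b", is_protein_binding = TRUE)
  expect_equal(nrow(influencers_of("L", net)), 0)
  # the protein keeps its substrate role in the binding reaction
  ep <- influencers_of("E", net)
  expect_true("product-of-consuming" %in% ep$type)
})

test_that("transporter edges require the node to be the transported species", {
  net <- network() |> add_metabolite("Xout") |> add_metabolite("X") |>
    add_gene_product("T") |>
    add_reaction("RT", "Xout", "X", enzymes = "T_p",
                 is_transport = TRUE, transported = "X")
  ex <- influencers_of("X", net)
  expect_true("transporter" %in% ex$type)
  expect_false(any(grepl("^enzyme-of", ex$type)))
  # the non-transported substrate sees a plain enzyme edge
  eo <- influencers_of("Xout", net)
  expect_true("enzyme-of-consuming" %in% eo$type)
  expect_false("transporter" %in% eo$type)
})

test_that("reversible reactions emit both readings with ambiguous sign", {
  net <- network() |> add_metabolite("A") |> add_metabolite("B") |>
    add_gene_product("E") |>
    add_reaction("R1", "A", "B", direction = "reversible", enzymes = "E_p")
  ea <- influencers_of("A", net)
  expect_setequal(
    paste(ea$type, ea$via),
    c("product-of-consuming R1:fwd", "enzyme-of-consuming R1:fwd",
      "reactant-of-producing R1:rev", "enzyme-of-producing R1:rev"))
  expect_true(all(ea$sign == "ambiguous"))
})

test_that("edge signs follow the policy and regulation records", {
  net <- network() |> add_gene_product("x") |> add_gene_product("tf") |>
    add_metabolite("S") |> add_metabolite("P") |>
    add_reaction("R1", "S", "P", enzymes = "x_p") |>
    add_metabolite("inh") |>
    add_regulation("g1", "tf_p", "x", "transcriptional", "-") |>
    add_regulation("g2", "inh", "x_p", "enzyme-modulation", "-")
  e <- influencers_of("x", net)
  expect_equal(e$sign[e$type == "transcriptional-regulator"], "-")
  expect_equal(e$sign[e$type == "enzyme-inhibitor"], "-")
  ep <- influencers_of("P", net)
  expect_equal(ep$sign[ep$type == "enzyme-of-producing"], "+")
  # a policy override changes the sign deterministically
  pol <- default_sign_policy()
  pol["enzyme-of-producing"] <- "-"
  e2 <- influencers_of("P", net, sign_policy = pol)
  expect_equal(e2$sign[e2$type == "enzyme-of-producing"], "-")
})

test_that("complex-component edges point at heteromultimer members", {
  net <- network() |> add_gene_product("a", "A_p") |>
    add_gene_product("b", "B_p") |>
    add_complex("AB", c(A_p = 1, B_p = 2)) |>
    add_complex("AA", c(A_p = 2))
  e <- influencers_of("AB", net)
  expect_setequal(e$to[e$type == "complex-component"], c("a", "b"))
  # homomultimer coalesces with its monomer: no self edge
  expect_equal(nrow(influencers_of("a", net)), 0)
})

test_that("edge costs match hand-evaluated formulas on small fixtures", {
  # reactant-of-producing with |Rx|=2 and |Ri|=3 -> 1 + (2+3)/20
  net <- make_substrate_fixture("reactant-of-producing", nx = 2, ni = 3)
  expect_equal(probe_cost(net, "reactant-of-producing"), 1.25)
  # complex-component is flat 0.1
  cxnet <- network() |> add_gene_product("a", "A_p") |>
    add_gene_product("b", "B_p") |> add_complex("X", c(A_p = 1, B_p = 1))
  e <- edge_cost(influencers_of("X", cxnet), cxnet)
  expect_true(all(e$cost[e$type == "complex-component"] == 0.1))
  # transcription-unit links are free
  tunet <- network() |> add_gene_product("X") |>
    add_transcription_unit("tu", "X")
  et <- edge_cost(influencers_of("X", tunet, "undirected"), tunet)
  expect_equal(et$cost[et$type == "transcription-unit"], 0)
})

test_that("input-entity membership overrides every formula except TU links", {
  types <- setdiff(influence_types(), "transcription-unit")
  for (ty in types) {
    pp <- planted_path_network(ty, decoys = 0, seed = 1)
    e <- influencers_of(pp$effect, pp$net, "undirected")
    e <- edge_cost(e, pp$net, input_entities = pp$condition)
    hit <- e[e$to == pp$condition & e$type == ty, , drop = FALSE]
    expect_equal(nrow(hit), 1, info = ty)
    expect_equal(hit$cost, 0.1, info = ty)
  }
  tunet <- network() |> add_gene_product("X") |>
    add_transcription_unit("tu", "X")
  et <- edge_cost(influencers_of("X", tunet, "undirected"), tunet,
                  input_entities = "tu")
  expect_equal(et$cost[et$type == "transcription-unit"], 0)
})

test_that("costs are non-decreasing in each specificity count", {
  for (role in c("reactant-of-producing", "reactant-of-consuming",
                 "product-of-consuming")) {
    grid <- expand.grid(nx = 0:3, ni = 0:3)
    costs <- mapply(function(nx, ni)
      probe_cost(make_substrate_fixture(role, nx, ni), role),
      grid$nx, grid$ni)
    m <- matrix(costs, 4, 4)
    expect_true(all(diff(m) >= 0) && all(t(diff(t(m))) >= 0), info = role)
  }
  enz <- vapply(0:3, function(k)
    probe_cost(make_enzyme_fixture(n_extra = k), "enzyme-of-producing"),
    numeric(1))
  expect_true(all(diff(enz) >= 0))
})

test_that("producing-side influences cost no more than consuming-side ones", {
  net <- network() |> add_metabolite("A") |> add_metabolite("X") |>
    add_metabolite("B") |> add_gene_product("E") |>
    add_reaction("Rp", "A", "X", enzymes = "E_p") |>
    add_reaction("Rc", c("X", "A2"), "B", enzymes = "E_p") |>
    add_metabolite("A2")
  e <- edge_cost(influencers_of("X", net), net)
  cost_of <- function(ty) e$cost[e$type == ty][1]
  expect_lte(cost_of("enzyme-of-producing"), cost_of("enzyme-of-consuming"))
  expect_lte(cost_of("reactant-of-producing"),
             cost_of("reactant-of-consuming"))
  expect_lte(cost_of("reactant-of-consuming"),
             cost_of("product-of-consuming"))
})

test_that("every licensed influence appears exactly once per provenance", {
  # independent scan straight off the network tables
  for (seed in c(3, 11)) {
    net <- generate_network(synth_params(seed = seed))
    lmap <- logical_node_map(net)
    ubi <- metregr:::resolve_ubiquitous(net$entities)
    names(ubi) <- net$entities$id
    lubi <- tapply(ubi, lmap[names(ubi)], any)
    expected <- list()
    note <- function(x, to, type, via) {
      if (x == to) return()
      expected[[length(expected) + 1]] <<- paste(x, to, type, via, sep = "|")
    }
    for (i in seq_len(nrow(net$reactions))) {
      r <- net$reactions[i, ]
      rid <- r$id
      lre <- unique(unname(lmap[r$reactants[[1]]]))
      lpr <- unique(unname(lmap[r$products[[1]]]))
      lenz <- unique(unname(lmap[r$enzymes[[1]]]))
      ltr <- unique(unname(lmap[r$transported[[1]]]))
      sml <- function(l) all(net$entities$kind[lmap == l] == "metabolite")
      # the binding-reaction exclusion gates X's substrate role only;
      # influencers are merely screened for ubiquity
      ok <- function(l) !isTRUE(lubi[[l]]) &&
        !(sml(l) && r$is_protein_binding)
      oki <- function(l) !isTRUE(lubi[[l]])
      sides <- list()
      if (r$direction %in% c("left-to-right", "reversible"))
        sides <- c(sides, list(list(from = lre, to = lpr,
          tag = if (r$direction == "reversible") paste0(rid, ":fwd") else rid)))
      if (r$direction %in% c("right-to-left", "reversible"))
        sides <- c(sides, list(list(from = lpr, to = lre,
          tag = if (r$direction == "reversible") paste0(rid, ":rev") else rid)))
      for (s in sides) {
        for (x in s$to) {  # x is produced
          if (!ok(x)) next
          for (i2 in setdiff(s$from, x)) if (oki(i2))
            note(x, i2, "reactant-of-producing", s$tag)
          if (!(r$is_transport && x %in% ltr))
            for (e2 in lenz) note(x, e2, "enzyme-of-producing", s$tag)
        }
        for (x in s$from) {  # x is consumed
          if (!ok(x)) next
          for (i2 in setdiff(s$from, x)) if (oki(i2))
            note(x, i2, "reactant-of-consuming", s$tag)
          for (i2 in setdiff(s$to, x)) if (oki(i2))
            note(x, i2, "product-of-consuming", s$tag)
          if (!(r$is_transport && x %in% ltr))
            for (e2 in lenz) note(x, e2, "enzyme-of-consuming", s$tag)
        }
      }
      if (r$is_transport) for (x in ltr) if (ok(x))
        for (e2 in lenz) note(x, e2, "transporter", rid)
    }
    for (i in seq_len(nrow(net$regulations))) {
      g <- net$regulations[i, ]
      ty <- switch(g$mode, transcriptional = "transcriptional-regulator",
                   translational = "translational-regulator",
                   `sigma-factor` = "sigma-factor", cofactor = "cofactor",
                   `enzyme-modulation` = if (g$sign == "+") "enzyme-activator"
                     else "enzyme-inhibitor")
      note(unname(lmap[g$regulatee]), unname(lmap[g$regulator]), ty, g$id)
    }
    for (i in seq_len(nrow(net$transcription_units))) {
      u <- net$transcription_units[i, ]
      for (gl in unique(unname(lmap[u$genes[[1]]])))
        note(gl, u$id, "transcription-unit", u$id)
    }
    hetero <- net$entities[net$entities$kind == "complex" &
      vapply(net$entities$components,
             function(cc) length(unique(names(cc))) > 1, logical(1)), ]
    for (i in seq_len(nrow(hetero))) {
      lx <- unname(lmap[hetero$id[i]])
      for (cl in setdiff(unique(unname(lmap[names(hetero$components[[i]])])),
                         lx))
        note(lx, cl, "complex-component", hetero$id[i])
    }
    got <- list()
    for (l in unique(unname(lmap))) {
      e <- influencers_of(l, net, "undirected")
      e <- e[e$to != e$from, , drop = FALSE]
      got <- c(got, paste(e$from, e$to, e$type, e$via, sep = "|"))
    }
    got <- unlist(got)
    expect_equal(anyDuplicated(got), 0)
    expect_sets_equal(got, unique(unlist(expected)))
  }
})
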