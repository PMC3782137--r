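surv <- liver_survey()
net <- build_network(surv)

test_that("the bipartite network has one node per entity and one edge per record", {
  expect_equal(sum(igraph::V(net)$type), 94)          # species
  expect_equal(sum(!igraph::V(net)$type), 7)          # disorders
  expect_equal(igraph::ecount(net), 121)
  expect_true(igraph::is_bipartite(net))
  # 2-coloring check: every edge joins the two modes
  ends <- igraph::ends(net, igraph::E(net))
  type <- igraph::V(net)$type[match(ends, igraph::V(net)$name)]
  dim(type) <- dim(ends)
  expect_true(all(xor(type[, 1], type[, 2])))

  # the heaviest edge carries the most-cited exclusive remedy
  w <- igraph::E(net)[igraph::V(net)["liver-related ailments"] %--%
                      igraph::V(net)["Taraxacum platycarpum Dahlst."]]$weight
  expect_equal(w, 192)

  single <- as_survey(data.frame(
    disorder = "a", scientific_name = "S p L.", mentions = 3, kind = "plant",
    used_parts = "leaf", preparations = "tea", application = "oral"
  ), aliases = NULL)
  g1 <- build_network(single)
  expect_equal(igraph::vcount(g1), 2)
  expect_equal(igraph::ecount(g1), 1)
})

test_that("species degree counts distinct disorders treated", {
  deg <- species_degree(net)
  get <- function(sp) deg$degree[deg$scientific_name == sp]
  expect_equal(get("Protaetia brevitarsis seulensis (Kolbe)"), 5)
  expect_equal(get("Oenanthe javanica (Blume) DC."), 4)
  expect_equal(get("Fomes fomentarius (L.: Fr.) Fr."), 3)
  expect_equal(get("Protaetia mandschuriensis (Schurhoff)"), 3)
  expect_equal(get("Cetonia pilifera (Motschulsky)"), 3)
  # ranking: degree desc, then strength desc, then name asc
  expect_equal(deg$scientific_name[1:2],
               c("Protaetia brevitarsis seulensis (Kolbe)",
                 "Oenanthe javanica (Blume) DC."))
  expect_true(all(diff(deg$degree) <= 0))
})

test_that("species strength equals the FL denominator for every species", {
  deg <- species_degree(net)
  fl <- compute_fl(surv)
  totals <- unique(fl[c("scientific_name", "n_total")])
  m <- match(deg$scientific_name, totals$scientific_name)
  expect_equal(deg$strength, as.numeric(totals$n_total[m]))
})

test_that("kind composition identifies all-animal neighborhoods and their exceptions", {
  comp <- disorder_kind_composition(net)
  fr <- comp[comp$disorder == "fatigue recovery", ]
  expect_equal(fr$n_animal, 3)
  expect_equal(fr$n_plant + fr$n_fungus, 0)
  expect_equal(fr$exceptions[[1]], character(0))

  lc <- comp[comp$disorder == "liver cirrhosis", ]
  expect_equal(lc$modal_kind, "animal")
  # the table records three non-animal remedies for cirrhosis: the two
  # well-known exceptions plus water dropwort (a plant cited twice)
  expect_setequal(lc$exceptions[[1]],
                  c("Bupleurum falcatum L.", "Fomes fomentarius (L.: Fr.) Fr.",
                    "Oenanthe javanica (Blume) DC."))

  single <- as_survey(data.frame(
    disorder = "a", scientific_name = "S p L.", mentions = 1, kind = "fungus",
    used_parts = "leaf", preparations = "tea", application = "oral"
  ), aliases = NULL)
  c1 <- disorder_kind_composition(build_network(single))
  expect_equal(c1$modal_kind, "fungus")
  expect_equal(c1$exceptions[[1]], character(0))
})

test_that("one-mode projections count shared neighbors", {
  pd <- project_one_mode(net, "disorder")
  el <- sorted_proj_df(pd)
  w <- el$weight[el$a == "liver cancer" & el$b == "liver cirrhosis"]
  expect_gte(w, 4)

  # disjoint neighborhoods project to no edges
  disjoint <- as_survey(data.frame(
    disorder = c("a", "b"), scientific_name = c("S p1 L.", "S p2 L."),
    mentions = 1, kind = "plant", used_parts = "leaf", preparations = "tea",
    application = "oral"
  ), aliases = NULL)
  expect_equal(igraph::ecount(project_one_mode(build_network(disjoint),
                                               "disorder")), 0)

  # identical species sets of size k give projection weight k
  k <- 4
  same <- as_survey(data.frame(
    disorder = rep(c("a", "b"), each = k),
    scientific_name = rep(sprintf("S p%d L.", 1:k), 2),
    mentions = 1, kind = "plant", used_parts = "leaf", preparations = "tea",
    application = "oral"
  ), aliases = NULL)
  ps <- project_one_mode(build_network(same), "disorder")
  expect_equal(igraph::E(ps)$weight, k)

  expect_error(project_one_mode(net, "sideways"),
               class = "ethnoquant_usage_error")
})

test_that("projections match the brute-force intersection oracle on random networks", {
  set.seed(99)
  for (rep in seq_len(30)) {
    tab <- random_table(n_disorders = sample(2:5, 1),
                        n_species = sample(3:12, 1))
    g <- build_network(tab)
    for (mode in c("species", "disorder")) {
      got <- sorted_proj_df(project_one_mode(g, mode))
      want <- oracle_projection(tab, mode)
      want <- want[order(want$a, want$b), ]
      rownames(want) <- NULL
      expect_equal(got, want)
      # symmetry is inherent in an undirected igraph; check weights positive
      expect_true(all(got$weight >= 1))
    }
  }
})

test_that("GraphML export round-trips nodes, edges and attributes", {
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(net, path)
  back <- import_graph(path)
  expect_equal(igraph::vcount(back), 101)
  expect_equal(igraph::ecount(back), 121)
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  expect_equal(sort(igraph::E(back)$weight), sort(igraph::E(net)$weight))
  m <- match(igraph::V(net)$name, igraph::V(back)$name)
  expect_equal(igraph::V(back)$kind[m], igraph::V(net)$kind)

  # empty network -> valid file with zero nodes
  empty <- build_network(liver_survey()[0, ])
  p0 <- withr::local_tempfile(fileext = ".graphml")
  export_graph(empty, p0)
  expect_equal(igraph::vcount(import_graph(p0)), 0)

  # 5-node toy graph structural round trip
  toy <- as_survey(data.frame(
    disorder = c("a", "a", "b"),
    scientific_name = c("S p1 L.", "S p2 L.", "S p3 L."),
    mentions = c(1, 2, 3), kind = "animal", used_parts = "larva",
    preparations = "dried", application = "oral"
  ), aliases = NULL)
  gt <- build_network(toy)
  pt <- withr::local_tempfile(fileext = ".graphml")
  export_graph(gt, pt)
  bt <- import_graph(pt)
  expect_equal(igraph::vcount(bt), 5)
  expect_equal(igraph::ecount(bt), 3)

  # edge list: three columns, weights preserved
  pe <- withr::local_tempfile(fileext = ".tsv")
  export_graph(gt, pe, format = "edgelist")
  el <- read.delim(pe)
  expect_equal(names(el), c("from", "to", "weight"))
  expect_equal(sort(el$weight), c(1, 2, 3))

  expect_error(export_graph(net, tempfile(), format = "dot"),
               class = "ethnoquant_usage_error")
})
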