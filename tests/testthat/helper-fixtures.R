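# A couple dozen hand-curated admixture histories with expected FP/TP labels for
# the model "target = source1 + source2". Labels were assigned by reading
# each topology against the classification rules; they are the authority
# the classifier must reproduce.
#
# Shared scaffold (dates in generations):
#   r(3000) -> O1, x
#   x(2500) -> O2, y
#   y(2000) -> sa, sb                  two stems
#   sa(1500) -> A1, sa2
#   sa2(700) -> A2, A2b
#   sb(1200) -> B1, aT
#   aT(100)  -> T                      pulse recipient on the B side
# Pulse into aT at date 100, donor chosen per fixture:
#   edge 10 = sa2 -> A2b (sampled A-side branch)
#   edge  9 = sa2 -> A2  (the other sampled A-side branch)
#   edge 13 = aT -> T    (target terminal; only as donor of later pulses)

fixture_scaffold <- function(donor_edge = 10L, prop = 0.4) {
  tb <- tibble::tibble
  nodes <- tb(
    node = c("O1", "O2", "A1", "A2", "A2b", "B1", "T",
             "r", "x", "y", "sa", "sa2", "sb", "aT"),
    date = c(0, 0, 0, 0, 0, 0, 0,
             3000, 2500, 2000, 1500, 700, 1200, 100),
    type = c(rep("leaf", 7), "root", rep("divergence", 5), "admixture")
  )
  edges <- tb(
    id = 1:13,
    from = c("r", "r", "x", "x", "y", "y", "sa", "sa", "sa2", "sa2",
             "sb", "sb", "aT"),
    to = c("O1", "x", "O2", "y", "sa", "sb", "A1", "sa2", "A2", "A2b",
           "B1", "aT", "T"),
    ne = 3000
  )
  list(nodes = nodes, edges = edges,
       admix = tb(node = "aT", donor_edge = donor_edge, prop = prop))
}

fixture_graphs <- function() {
  tb <- tibble::tibble
  g_of <- function(s) admixture_graph(s$nodes, s$edges, s$admix)
  out <- list()
  put <- function(name, label, rule, graph, sources, target = "T") {
    out[[name]] <<- list(name = name, label = label, rule = rule,
                         graph = graph, sources = sources, target = target)
  }

  ## TP cases: proxies representing the two distinct true sources ---------
  s <- fixture_scaffold()
  put("tp_sisters", "TP", NA, g_of(s), c("A2b", "B1"))
  put("tp_deep_sister", "TP", NA, g_of(s), c("A2", "B1"))
  put("tp_stem_cousin", "TP", NA, g_of(s), c("A1", "B1"))
  s2 <- fixture_scaffold(donor_edge = 9L, prop = 0.3)
  put("tp_other_branch_donor", "TP", NA, g_of(s2), c("A2", "B1"))
  put("tp_other_branch_far", "TP", NA, g_of(s2), c("A1", "B1"))

  ## rule 1: a proxy strictly cladal with the target ----------------------
  # T gets a sibling Tsib below the admixture event
  s3 <- fixture_scaffold()
  nodes_c <- dplyr::bind_rows(
    s3$nodes,
    tb(node = c("tC", "Tsib"), date = c(50, 0),
       type = c("divergence", "leaf"))
  )
  edges_c <- s3$edges
  edges_c$to[edges_c$id == 13] <- "tC"
  edges_c <- dplyr::bind_rows(
    edges_c, tb(id = c(14L, 15L), from = "tC", to = c("T", "Tsib"),
                ne = 3000)
  )
  g_clad <- admixture_graph(nodes_c, edges_c, s3$admix)
  put("fp1_sibling_proxy", "FP", 1L, g_clad, c("Tsib", "B1"))
  put("fp1_sibling_with_a_side", "FP", 1L, g_clad, c("Tsib", "A2"))
  put("fp1_sibling_with_outgroup", "FP", 1L, g_clad, c("Tsib", "O1"))

  ## rule 2: a proxy descends from flow leaving the target lineage --------
  # second pulse from the target terminal edge into B1's branch
  s4 <- fixture_scaffold()
  nodes_r2 <- dplyr::bind_rows(
    s4$nodes, tb(node = "aB", date = 60, type = "admixture")
  )
  edges_r2 <- s4$edges
  edges_r2$to[edges_r2$id == 11] <- "aB"
  edges_r2 <- dplyr::bind_rows(
    edges_r2, tb(id = 14L, from = "aB", to = "B1", ne = 3000)
  )
  admix_r2 <- dplyr::bind_rows(
    s4$admix, tb(node = "aB", donor_edge = 13L, prop = 0.2)
  )
  g_r2 <- admixture_graph(nodes_r2, edges_r2, admix_r2)
  put("fp2_backflow", "FP", 2L, g_r2, c("A2b", "B1"))
  put("fp2_backflow_other_a", "FP", 2L, g_r2, c("A2", "B1"))
  put("fp2_backflow_stem_proxy", "FP", 2L, g_r2, c("A1", "B1"))
  # flow from the shared stem *above* the admixture event is not rule 2
  nodes_r2b <- nodes_r2
  nodes_r2b$date[nodes_r2b$node == "aB"] <- 150
  admix_r2b <- dplyr::bind_rows(
    s4$admix, tb(node = "aB", donor_edge = 12L, prop = 0.2)
  )
  g_r2b <- admixture_graph(nodes_r2b, edges_r2, admix_r2b)
  put("tp_stem_backflow", "TP", NA, g_r2b, c("A2b", "B1"))

  ## rule 3: symmetric or same-side proxies -------------------------------
  s5 <- fixture_scaffold()
  put("fp3_outgroup_for_a", "FP", 3L, g_of(s5), c("O2", "B1"))
  put("fp3_outgroup_for_b", "FP", 3L, g_of(s5), c("O1", "A2b"))
  put("fp3_both_a_side", "FP", 3L, g_of(s5), c("A2", "A2b"))
  put("fp3_both_a_side_far", "FP", 3L, g_of(s5), c("A1", "A2"))

  ## rule 4: diluted (admixed) proxy --------------------------------------
  # P hangs off the outgroup side and receives a fraction of A2-branch
  # ancestry; that fraction decides rule 4
  mk_diluted <- function(p_admix) {
    s <- fixture_scaffold()
    nodes <- dplyr::bind_rows(
      s$nodes,
      tb(node = c("oP", "aP", "P"), date = c(2200, 300, 0),
         type = c("divergence", "admixture", "leaf"))
    )
    edges <- s$edges
    edges$to[edges$id == 3] <- "oP"
    edges <- dplyr::bind_rows(
      edges,
      tb(id = 14L, from = "oP", to = "O2", ne = 3000),
      tb(id = 15L, from = "oP", to = "aP", ne = 3000),
      tb(id = 16L, from = "aP", to = "P", ne = 3000)
    )
    admix <- dplyr::bind_rows(
      s$admix, tb(node = "aP", donor_edge = 9L, prop = p_admix)
    )
    admixture_graph(nodes, edges, admix)
  }
  put("fp4_diluted_proxy", "FP", 4L, mk_diluted(0.30), c("P", "B1"))
  put("fp4_strongly_diluted", "FP", 4L, mk_diluted(0.15), c("P", "B1"))
  put("fp4_mid_diluted", "FP", 4L, mk_diluted(0.25), c("P", "B1"))
  put("tp_barely_enough", "TP", NA, mk_diluted(0.45), c("P", "B1"))

  ## rule 5: deep-branching ghost source ----------------------------------
  # the donor is an unsampled lineage hanging off the deep outgroup stem
  s6 <- fixture_scaffold()
  nodes_r5 <- dplyr::bind_rows(
    s6$nodes,
    tb(node = c("gsplit", "ghost"), date = c(2800, 50),
       type = c("divergence", "divergence"))
  )
  edges_r5 <- s6$edges
  edges_r5$to[edges_r5$id == 1] <- "gsplit"
  edges_r5 <- dplyr::bind_rows(
    edges_r5,
    tb(id = 14L, from = "gsplit", to = "O1", ne = 3000),
    tb(id = 15L, from = "gsplit", to = "ghost", ne = 3000)
  )
  admix_r5 <- tb(node = "aT", donor_edge = 15L, prop = 0.4)
  g_r5 <- admixture_graph(nodes_r5, edges_r5, admix_r5)
  put("fp5_ghost_source", "FP", 5L, g_r5, c("A2b", "B1"))
  put("fp5_ghost_source_alt", "FP", 5L, g_r5, c("A1", "B1"))
  put("fp5_ghost_outgroup_proxy", "FP", 5L, g_r5, c("O1", "B1"))

  ## unadmixed target ------------------------------------------------------
  put("no_admix_target", "no-admixture", NA, g_of(s), c("A2b", "T"),
      target = "B1")

  out
}
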