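# A hand-built world where two adjacent positions are missing and each one's
# coherence signal routes through the other: A's pool resolves via its known
# neighbor K1 and B; B's only neighbor is A, so B is only identifiable once
# A carries its true gene.
two_node_world <- function() {
  dag <- ontology_dag(
    list(bp = character(0),
         t1 = "bp", t2 = "bp", t3 = "bp", t4 = "bp",
         u1 = "bp", u2 = "bp", u3 = "bp", u4 = "bp"),
    stats::setNames(rep("BP", 9),
                    c("bp", "t1", "t2", "t3", "t4", "u1", "u2", "u3", "u4")))
  ann <- make_ann(
    K1 = c("t1", "t2"),
    a_true = c("t1", "t2", "t3", "t4"),
    b_true = c("t3", "t4"),
    a_d1 = "u1", a_d2 = "u2", b_d1 = "u3", b_d2 = "u4")
  freq <- build_term_frequencies(dag, ann)
  cooc <- build_cooccurrence(ann)
  net <- graph_as_network(c("K1", "A", "B"),
                          rbind(c("K1", "A"), c("A", "B")))
  scorers <- make_scorers(dag, ann, freq, cooc)["CAS"]
  # a fixed coherence-only combiner: high mean CAS -> probability near 1
  model <- structure(list(beta = c(CAS_GTOM1_N1 = 1.5), intercept = 2,
                          C = 1, negative_weight = 0.001,
                          feature_cols = "CAS_GTOM1_N1"),
                     class = "combiner_model")
  list(net = net, scorers = scorers, model = model,
       pools = list(A = c("a_true", "a_d1", "a_d2"),
                    B = c("b_true", "b_d1", "b_d2")),
       truth = c(A = "a_true", B = "b_true"))
}
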