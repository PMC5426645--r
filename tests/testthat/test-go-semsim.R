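toy_obo_lines <- c(
  "format-version: 1.2", "",
  "[Term]", "id: GO:0000001", "name: root",
  "namespace: biological_process", "",
  "[Term]", "id: GO:0000002", "name: child a",
  "namespace: biological_process", "is_a: GO:0000001 ! root", "",
  "[Term]", "id: GO:0000003", "name: child b",
  "namespace: biological_process", "is_a: GO:0000001", "alt_id: GO:0000099", "",
  "[Term]", "id: GO:0000004", "name: grandchild",
  "namespace: biological_process", "relationship: part_of GO:0000002 ! child a", "",
  "[Term]", "id: GO:0000005", "name: gone",
  "namespace: biological_process", "is_a: GO:0000001", "is_obsolete: true")

test_that("obo stanzas parse with typed links, alt ids and obsolete flags", {
  dag <- parse_obo(write_tmp(toy_obo_lines, ".obo"))
  expect_length(dag$terms, 5L)
  expect_equal(sum(lengths(lapply(dag$terms, `[[`, "parents"))), 4L)
  expect_identical(dag$terms[["GO:0000004"]]$relation, "part_of")
  expect_identical(edgefill:::resolve_term("GO:0000099", dag), "GO:0000003")
  expect_true(dag$terms[["GO:0000005"]]$obsolete)
  expect_error(svalues("GO:0000005", dag), "obsolete")
})

test_that("a cyclic ontology is rejected naming an offending term", {
  expect_error(dag_from_spec(list(a = c(is_a = "b"), b = c(is_a = "a"))),
               "cycle.*(a|b)")
})

test_that("cross-namespace parent links are dropped", {
  lines <- c("format-version: 1.2", "",
             "[Term]", "id: X:1", "namespace: biological_process", "",
             "[Term]", "id: X:2", "namespace: molecular_function",
             "is_a: X:1")
  dag <- edgefill:::go_dag_from_lines(lines)
  expect_length(dag$terms[["X:2"]]$parents, 0L)
})

test_that("gaf rows are filtered by aspect, NOT qualifier and obsolete terms", {
  dag <- parse_obo(write_tmp(toy_obo_lines, ".obo"))
  gaf <- write_tmp(c("!gaf-version: 2.1",
                     gaf_row("P1", "GO:0000002", aspect = "P"),
                     gaf_row("P1", "GO:0000003", aspect = "F"),
                     gaf_row("P2", "GO:0000002", qualifier = "NOT"),
                     gaf_row("P2", "GO:0000099"),          # alt id
                     gaf_row("P2", "GO:0000099"),          # duplicate
                     gaf_row("P3", "GO:0000005")), ".gaf") # obsolete
  ann <- suppressMessages(read_gaf(gaf, "BP", dag))
  expect_identical(ann[["P1"]], "GO:0000002")
  expect_identical(ann[["P2"]], "GO:0000003")
  expect_null(ann[["P3"]])
})

test_that("s-values follow the weighted chain and max-path rules", {
  chain <- dag_from_spec(list(root = character(),
                              p = c(is_a = "root"),
                              a = c(is_a = "p")))
  s <- svalues("a", chain)
  expect_equal(s[["a"]], 1)
  expect_equal(s[["p"]], 0.8)
  expect_equal(s[["root"]], 0.64)
  expect_equal(svalues("root", chain), c(root = 1))
  # diamond: paths is_a/is_a (0.64) vs part_of/is_a-ish (0.48): max wins
  diamond <- dag_from_spec(list(
    root = character(),
    l = c(is_a = "root"), r = c(is_a = "root"),
    a = c(is_a = "l", part_of = "r")))
  s <- svalues("a", diamond)
  expect_equal(s[["root"]], max(0.8 * 0.8, 0.6 * 0.8))
  expect_equal(s, brute_svalues("a", diamond)[names(s)])
})

test_that("s-value dynamic program equals exhaustive path enumeration", {
  for (i in 1:40) {
    dag <- dag_from_spec(random_dag_spec(sample(5:30, 1L), seed = 100 + i))
    anchor <- sample(names(dag$terms), 1L)
    got <- svalues(anchor, dag)
    want <- brute_svalues(anchor, dag)
    expect_setequal(names(got), names(want))
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
})

test_that("term similarity is the common-ancestor mass ratio", {
  dag <- dag_from_spec(list(root = character(),
                            a = c(is_a = "root"), b = c(is_a = "root")))
  expect_equal(term_sim("a", "a", dag), 1)
  # siblings share only the root: hand-computed ratio
  expect_equal(term_sim("a", "b", dag), (0.8 + 0.8) / (1.8 + 1.8))
  expect_equal(term_sim("a", "b", dag), term_sim("b", "a", dag))
  deep <- dag_from_spec(list(root = character(), p = c(is_a = "root"),
                             a = c(is_a = "p"), b = c(is_a = "p")))
  sa <- brute_svalues("a", deep); sb <- brute_svalues("b", deep)
  common <- intersect(names(sa), names(sb))
  expect_equal(term_sim("a", "b", deep),
               sum(sa[common] + sb[common]) / (sum(sa) + sum(sb)))
})

test_that("cross-namespace term pairs are rejected", {
  lines <- c("format-version: 1.2", "",
             "[Term]", "id: X:1", "namespace: biological_process", "",
             "[Term]", "id: X:2", "namespace: molecular_function")
  dag <- edgefill:::go_dag_from_lines(lines)
  expect_error(term_sim("X:1", "X:2", dag), "namespace")
})

test_that("protein similarity: identity, unannotated zero, single-term case", {
  dag <- dag_from_spec(list(root = character(), p = c(is_a = "root"),
                            a = c(is_a = "p"), b = c(is_a = "p"),
                            c = c(part_of = "root")))
  ann <- annotation_map(list(u = c("a", "b"), v = c("a", "b"),
                             w = "b", x = "c"), dag)
  expect_equal(protein_go_sim("u", "v", ann, dag), 1)
  expect_equal(protein_go_sim("u", "missing", ann, dag), 0)
  expect_equal(protein_go_sim("w", "x", ann, dag), term_sim("b", "c", dag))
  expect_equal(protein_go_sim("u", "w", ann, dag),
               protein_go_sim("w", "u", ann, dag))
})

test_that("protein similarity equals the brute-force oracle on random cases", {
  for (i in 1:30) {
    dag <- dag_from_spec(random_dag_spec(sample(6:25, 1L), seed = 500 + i))
    terms <- names(dag$terms)
    ann <- annotation_map(
      list(u = sample(terms, sample(1:3, 1L)),
           v = sample(terms, sample(1:3, 1L))), dag)
    got <- protein_go_sim("u", "v", ann, dag)
    expect_equal(got, brute_protein_sim("u", "v", ann, dag),
                 tolerance = 1e-12)
    expect_gte(got, 0); expect_lte(got, 1 + 1e-12)
  }
})

test_that("adding an unrelated annotation branch never raises similarity", {
  # u sits in one subtree; v gains leaves from a disjoint subtree
  dag <- dag_from_spec(list(
    root = character(),
    s1 = c(is_a = "root"), s2 = c(is_a = "root"),
    a = c(is_a = "s1"), b = c(is_a = "s1"),
    z1 = c(is_a = "s2"), z2 = c(is_a = "s2")))
  base <- annotation_map(list(u = "a", v = "b"), dag)
  diluted <- annotation_map(list(u = "a", v = c("b", "z1")), dag)
  diluted2 <- annotation_map(list(u = "a", v = c("b", "z1", "z2")), dag)
  s0 <- protein_go_sim("u", "v", base, dag)
  s1 <- protein_go_sim("u", "v", diluted, dag)
  s2 <- protein_go_sim("u", "v", diluted2, dag)
  expect_lte(s1, s0)
  expect_lte(s2, s1)
})
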