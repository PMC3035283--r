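test_that("offsp_n reproduces the published normalization endpoints", {
  # published cells with the printed root offspring count M = 8267
  expect_equal(round(offsp_n(0, 8267), 2), 9.02)
  expect_equal(round(offsp_n(1, 8267), 2), 8.33)
  expect_equal(round(offsp_n(5, 8267), 2), 7.23)
  expect_equal(offsp_n(8267, 8267), 0)
  # closed form and monotonicity
  expect_equal(offsp_n(0, 8267), log(8268))
  k <- 0:100
  expect_true(all(diff(offsp_n(k, 8267)) < 0))
  expect_error(offsp_n(9000, 8267), class = "bounds_error")
  expect_error(offsp_n(-1, 10), class = "bounds_error")
  expect_error(offsp_n(1, 0), class = "bounds_error")
})

test_that("go_proportion reproduces the published cells and handles 0/0", {
  expect_equal(go_proportion(0, 8), 1)
  expect_equal(round(go_proportion(1, 5), 2), 0.83)
  expect_equal(round(go_proportion(5, 2), 2), 0.29)
  expect_true(is.na(go_proportion(0, 0)))
  expect_error(go_proportion(-1, 2), class = "bounds_error")
  grid <- expand.grid(off = 0:6, anc = 0:6)
  vals <- go_proportion(grid$off, grid$anc)
  expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
})

test_that("information_content is -log2(p) with the right edge states", {
  expect_equal(round(information_content(4 / 11), 1), 1.5)
  expect_equal(information_content(1), 0)
  expect_equal(information_content(0.25), 2)
  expect_true(is.na(information_content(0)))
  expect_error(information_content(1.5), class = "bounds_error")
  expect_error(information_content(-0.1), class = "bounds_error")
})

test_that("term_probability follows the three counting steps on the toy fixture", {
  fx <- figure1_fixture()
  expect_equal(term_probability(fx$dag, fx$ann, "GO:Term_3"), 4 / 11)
  expect_equal(term_probability(fx$dag, fx$ann, "GO:Term_1"), 1)
  # a leaf with no annotated unit in its closure has p = 0 and undefined IC
  dag2 <- build_dag(list(c("A", "R"), c("L", "A")), root_id = "R")
  ann2 <- annotation_set(list(G1 = "A"), dag2)
  expect_equal(term_probability(dag2, ann2, "L"), 0)
  tab2 <- compute_all(dag2, ann2)
  expect_true(is.na(tab2$ic[tab2$term_id == "L"]))
  expect_error(term_probability(fx$dag, fx$ann, "nope"),
               class = "unknown_term_error")
})

test_that("count_mode=sum reproduces the literal add-the-counts reading", {
  # one unit annotated to both a term and its child: counted once under
  # "unique", twice under "sum"
  dag <- build_dag(list(c("A", "R"), c("B", "A")), root_id = "R")
  ann <- annotation_set(list(G1 = c("A", "B"), G2 = "R"), dag)
  expect_equal(term_probability(dag, ann, "A", count_mode = "unique"), 1 / 2)
  expect_equal(term_probability(dag, ann, "A", count_mode = "sum"), 2 / 2)
  tab <- compute_all(dag, ann, metric_config(count_mode = "sum"))
  expect_equal(tab$p[tab$term_id == "A"], 1)
  # toy fixture has no overlap, so both modes agree everywhere
  fx <- figure1_fixture()
  tu <- compute_all(fx$dag, fx$ann, metric_config(count_mode = "unique"))
  ts <- compute_all(fx$dag, fx$ann, metric_config(count_mode = "sum"))
  expect_equal(tu$p, ts$p)
})

test_that("compute_all fills the toy fixture and respects missing annotations", {
  fx <- figure1_fixture()
  tab <- compute_all(fx$dag, fx$ann)
  row3 <- tab[tab$term_id == "GO:Term_3", ]
  expect_equal(row3$p, 4 / 11)
  expect_equal(round(row3$ic, 2), 1.46)
  expect_equal(row3$n_ancestors, 1L)

  bare <- compute_all(fx$dag)
  expect_true(all(is.na(bare$p)) && all(is.na(bare$ic)))
  expect_false(anyNA(bare$offsp_n))

  expect_error(compute_all(fx$dag, cfg = metric_config(max_offspring = 2)),
               class = "bounds_error")
  over <- compute_all(fx$dag, fx$ann, metric_config(max_offspring = 8267))
  expect_equal(round(over$offsp_n[over$n_offspring == 0][1], 2), 9.02)
})

test_that("a single-node ontology degenerates gracefully", {
  tab <- compute_all(build_dag(list(), root_id = "R"))
  expect_equal(tab$offsp_n, 0)
  expect_true(is.na(tab$go_prop))
  expect_equal(tab$n_ancestors, 0L)
})

test_that("compute_all agrees with naive per-term recomputation", {
  for (seed in c(4L, 9L)) {
    g <- generate_synthetic(synthetic_spec(n_terms = 55, n_units = 80,
                                           seed = seed))
    tab <- compute_all(g$dag, g$ann)
    for (id in dag_terms(g$dag)) {
      row <- tab[tab$term_id == id, ]
      anc <- ancestor_set(g$dag, id)
      off <- offspring_set(g$dag, id)
      expect_equal(row$n_ancestors, length(anc))
      expect_equal(row$n_offspring, length(off))
      # naive recount: enumerate the closure and scan every unit
      closure <- c(id, off)
      n_hit <- sum(vapply(g$ann$by_gene, function(ts)
        any(ts %in% closure), FALSE))
      expect_equal(row$p, n_hit / g$ann$n_genes)
    }
  }
})

test_that("metrics are monotone along every edge of seeded DAGs", {
  for (seed in c(7L, 13L)) {
    g <- generate_synthetic(synthetic_spec(n_terms = 60, n_units = 150,
                                           seed = seed))
    tab <- compute_all(g$dag, g$ann)
    rownames(tab) <- tab$term_id
    for (ch in dag_terms(g$dag)) {
      for (pa in g$dag$parents[[ch]]) {
        expect_gte(tab[pa, "p"], tab[ch, "p"])
        if (!is.na(tab[ch, "ic"]) && !is.na(tab[pa, "ic"])) {
          expect_gte(tab[ch, "ic"], tab[pa, "ic"])
        }
        expect_gt(tab[ch, "offsp_n"], tab[pa, "offsp_n"])
        expect_gt(tab[ch, "n_ancestors"], tab[pa, "n_ancestors"])
      }
    }
    M <- max(tab$n_offspring)
    expect_true(all(tab$offsp_n >= 0 & tab$offsp_n <= log(M + 1)))
    expect_true(all(is.na(tab$go_prop) | (tab$go_prop >= 0 & tab$go_prop <= 1)))
    expect_equal(tab[g$dag$root_id, "ic"], 0)
  }
})
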