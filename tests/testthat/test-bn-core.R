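test_that("acyclicity is decided correctly", {
  expect_true(is_acyclic(new_dag(c("A", "B", "C"),
                                 rbind(c("A", "B"), c("B", "C")))))
  expect_false(is_acyclic(new_dag(c("A", "B"),
                                  rbind(c("A", "B"), c("B", "A")),
                                  check_acyclic = FALSE)))
  expect_true(is_acyclic(new_dag(character())))
  expect_error(new_dag(c("A", "B"), rbind(c("A", "B"), c("B", "A"))),
               "cycle")
  expect_error(new_dag("A", rbind(c("A", "A"))), "self-loop")
  expect_error(new_dag("A", rbind(c("A", "B"))), "endpoint")
})

test_that("joint probability is the product of CPT lookups", {
  one <- new_discrete_bn(new_dag("A"), list(
    A = new_cpt("A", character(), c("0", "1"), list(), c(0.7, 0.3))))
  expect_equal(joint_probability(one, list(A = "1")), 0.3)

  dag <- new_dag(c("A", "B"), rbind(c("A", "B")))
  bn <- new_discrete_bn(dag, list(
    A = new_cpt("A", character(), c("0", "1"), list(), c(0.5, 0.5)),
    B = new_cpt("B", "A", c("0", "1"), list(A = c("0", "1")),
                cbind(c(0.9, 0.1), c(0.1, 0.9)))))
  expect_equal(joint_probability(bn, list(A = "1", B = "1")), 0.45)
  expect_error(joint_probability(bn, list(A = "1", B = "2")), "domain")
})

test_that("random small networks normalize to one under enumeration", {
  set.seed(3)
  for (i in 1:10) {
    bn <- random_binary_bn(4)
    expect_equal(sum(dbnsurv:::enumerate_joint(bn)$prob), 1,
                 tolerance = 1e-9)
  }
})

test_that("CPT validation rejects malformed tables", {
  expect_error(new_cpt("A", character(), c("0", "1"), list(), c(0.6, 0.6)),
               "sum to 1")
  expect_error(new_cpt("A", character(), c("0", "1"), list(), c(1.2, -0.2)),
               "lie in")
})

test_that("edge constraints validate and are checkable", {
  expect_error(edge_constraints(whitelist = rbind(c("A", "B")),
                                blacklist = rbind(c("A", "B"))),
               "overlap")
  expect_error(edge_constraints(whitelist = rbind(c("A", "B"),
                                                  c("B", "A"))),
               "cyclic")
  cst <- edge_constraints(whitelist = rbind(c("A", "B")),
                          blacklist = rbind(c("C", "A")))
  g_ok <- new_dag(c("A", "B", "C"), rbind(c("A", "B"), c("A", "C")))
  g_bad <- new_dag(c("A", "B", "C"), rbind(c("A", "B"), c("C", "A")))
  expect_true(satisfies_constraints(g_ok, cst))
  expect_false(satisfies_constraints(g_bad, cst))
})

make_chain_tbn <- function(p1, p_stay) {
  prior <- new_discrete_bn(new_dag("N@1"), list(
    `N@1` = new_cpt("N@1", character(), c("0", "1"), list(),
                    c(1 - p1, p1))))
  tdag <- new_dag(c("N@1", "N@2"), rbind(c("N@1", "N@2")))
  trans <- new_discrete_bn(tdag, list(
    `N@1` = new_cpt("N@1", character(), c("0", "1"), list(), c(0.5, 0.5)),
    `N@2` = new_cpt("N@2", "N@1", c("0", "1"), list(`N@1` = c("0", "1")),
                    cbind(c(1, 0), c(1 - p_stay, p_stay)))))
  new_two_slice_tbn(prior, trans)
}

test_that("unrolled joint reduces to the prior at T = 1 and multiplies
           transition factors afterwards", {
  tbn <- make_chain_tbn(1, 0.8)
  expect_equal(unroll_joint(tbn, list(`N@1` = "1"), T = 1), 1)
  traj <- list(`N@1` = "1", `N@2` = "1", `N@3` = "1")
  expect_equal(unroll_joint(tbn, traj, T = 3), 0.8^2)
  expect_error(unroll_joint(tbn, list(`N@1` = "1"), T = 2), "incomplete")
})

test_that("unrolled joint matches enumeration of the unrolled static BN", {
  set.seed(9)
  p1 <- 0.7
  a <- runif(1, 0.2, 0.9)
  b <- runif(1, 0.05, 0.5)
  tbn <- make_chain_tbn(p1, a)
  # build the unrolled 3-slice static chain with transition rows (stay = a,
  # revive = b) to exercise a non-absorbing chain too
  tdag <- new_dag(c("N@1", "N@2"), rbind(c("N@1", "N@2")))
  trans <- new_discrete_bn(tdag, list(
    `N@1` = new_cpt("N@1", character(), c("0", "1"), list(), c(0.5, 0.5)),
    `N@2` = new_cpt("N@2", "N@1", c("0", "1"), list(`N@1` = c("0", "1")),
                    cbind(c(1 - b, b), c(1 - a, a)))))
  tbn <- new_two_slice_tbn(tbn$prior, trans)
  unrolled <- new_discrete_bn(
    new_dag(c("N@1", "N@2", "N@3"),
            rbind(c("N@1", "N@2"), c("N@2", "N@3"))),
    list(`N@1` = tbn$prior$cpts[["N@1"]],
         `N@2` = new_cpt("N@2", "N@1", c("0", "1"),
                         list(`N@1` = c("0", "1")),
                         trans$cpts[["N@2"]]$prob),
         `N@3` = new_cpt("N@3", "N@2", c("0", "1"),
                         list(`N@2` = c("0", "1")),
                         trans$cpts[["N@2"]]$prob)))
  tot <- 0
  for (v1 in c("0", "1")) for (v2 in c("0", "1")) for (v3 in c("0", "1")) {
    traj <- list(`N@1` = v1, `N@2` = v2, `N@3` = v3)
    expect_equal(unroll_joint(tbn, traj, T = 3),
                 joint_probability(unrolled, traj), tolerance = 1e-12)
    tot <- tot + unroll_joint(tbn, traj, T = 3)
  }
  expect_equal(tot, 1, tolerance = 1e-9)
})

test_that("CPT text export has one row per parent combination", {
  cpt <- new_cpt("B", "A", c("0", "1"), list(A = c("a", "b", "c")),
                 cbind(c(0.2, 0.8), c(0.5, 0.5), c(0.9, 0.1)))
  path <- file.path(tempdir(), "cpt.tsv")
  write_cpt(cpt, path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  expect_equal(nrow(tab), 3)
  expect_equal(tab[["1"]], c(0.8, 0.5, 0.1))
})

test_that("DAG round-trips through DOT and edge-list exports", {
  g <- new_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  dot <- file.path(tempdir(), "g.dot")
  el <- file.path(tempdir(), "g.tsv")
  write_dot(g, dot)
  expect_true(any(grepl("\"A\" -> \"B\"", readLines(dot))))
  write_edge_list(g, el)
  expect_equal(unname(read_edge_list(el)), unname(g$edges))
})
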