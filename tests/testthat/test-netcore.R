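test_that("network construction validates ids, declarations and stoichiometry", {
  net <- chain_network()
  expect_s3_class(net, "efm_network")
  expect_identical(names(net$reactions), c("R1", "R2"))

  expect_error(
    build_network(list(metabolite("A", external = TRUE)),
                  list(reaction("R1", c(A = -1, X = 1)))),
    "undeclared metabolite.*X")
  expect_error(
    build_network(list(metabolite("A"), metabolite("A")), list()),
    "duplicate metabolite")
  expect_error(
    build_network(list(metabolite("A", external = TRUE), metabolite("B")),
                  list(reaction("R1", c(A = -1, B = 1)),
                       reaction("R1", c(B = -1, A = 1)))),
    "duplicate reaction")
  expect_error(reaction("R1", numeric(0)), "empty stoichiometry")
  expect_error(reaction("R1", c(A = 0)), "zero coefficient")
  # isolated internal metabolites are rejected
  expect_error(
    build_network(list(metabolite("A", external = TRUE), metabolite("B"),
                       metabolite("Lost")),
                  list(reaction("R1", c(A = -1, B = 1)),
                       reaction("R2", c(B = -1, A = 1)))),
    "Lost")
})

test_that("stoichiometric matrix has internal rows in declaration order", {
  net <- chain_network()
  S <- stoichiometric_matrix(net)
  expect_identical(dim(S), c(1L, 2L))
  expect_identical(rownames(S), "B")
  expect_identical(unname(S["B", ]), c(1, -1))

  # construction is deterministic: identical inputs, identical dimnames
  S2 <- stoichiometric_matrix(chain_network())
  expect_identical(S, S2)
})

test_that("network with zero internal metabolites gives a 0-row matrix and one mode per irreversible reaction", {
  net <- build_network(
    list(metabolite("A", external = TRUE), metabolite("B", external = TRUE)),
    list(reaction("R1", c(A = -1, B = 1)),
         reaction("R2", c(B = -1, A = 1))))
  S <- stoichiometric_matrix(net)
  expect_identical(dim(S), c(0L, 2L))
  efms <- enumerate_efms(net)
  expect_identical(support_keys(efms), c("R1", "R2"))
})

test_that("overall reaction nets external stoichiometry and scales homogeneously", {
  net <- chain_network()
  ov <- overall_reaction(c(R1 = 1, R2 = 1), net)
  expect_identical(ov, c(Aext = -1, Cext = 1))
  # invariant under positive scaling up to the same factor
  expect_identical(overall_reaction(c(R1 = 3, R2 = 3), net), 3 * ov)
  expect_error(overall_reaction(c(1, 1, 1), net), "does not match")
})

test_that("internalizing an external metabolite adds exactly one row and keeps all columns", {
  net <- fixture("tca_classical")$network
  S0 <- stoichiometric_matrix(net)
  net2 <- set_external(net, "CO2", external = FALSE)
  S1 <- stoichiometric_matrix(net2)
  expect_identical(nrow(S1), nrow(S0) + 1L)
  expect_identical(colnames(S1), colnames(S0))
  expect_true("CO2" %in% rownames(S1))
})

test_that("drop_reactions removes columns and prunes unreferenced species", {
  net <- fixture("tca_classical")$network
  ko <- drop_reactions(net, "Glyco")
  expect_false("Glyco" %in% names(ko$reactions))
  expect_false("Glc" %in% ko$metabolites$id)   # Glc only fed Glyco
  expect_error(drop_reactions(net, "nope"), "unknown reaction")
})
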