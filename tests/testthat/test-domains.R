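test_that("domain network specifications are validated", {
  doms <- list(domain_annotation("D1", "g", "c.1.1", "active site"))
  sp <- list(metabolite("A", external = TRUE), metabolite("B"),
             metabolite("C", external = TRUE))
  steps <- list(reaction("S1", c(A = -1, B = 1), catalysts = "D1"),
                reaction("S2", c(B = -1, C = 1)))
  spec <- domain_network_spec(doms, sp, steps,
                              enzyme_map = list(enz = c("S1", "S2")))
  net <- build_domain_network(spec)
  expect_s3_class(net, "domain_network")
  expect_length(enumerate_efms(net)$modes, 1L)

  bad <- list(reaction("S1", c(A = -1, B = 1), catalysts = "X9"))
  expect_error(domain_network_spec(doms, sp, bad), "undeclared domain.*X9")
  expect_error(
    domain_network_spec(doms, sp, list(steps[[1]], steps[[1]])),
    "duplicate step")
  expect_error(
    domain_network_spec(doms, sp, steps, enzyme_map = list(enz = "S9")),
    "unknown step")
  expect_error(domain_annotation("D", "g", "f", "x", role = "other"))
})

test_that("reactions_of_domain finds catalytic and binding attachments", {
  net <- fixture("tca_domain")$network
  expect_identical(reactions_of_domain(net, "PdhD2"), c("R5", "R6", "R7"))
  # catalytic domain shared by PDH and ODH dihydrolipoamide reoxidation
  expect_identical(reactions_of_domain(net, "PdhD3"), c("R4", "R6", "R14"))
  # binding domain species: the SucC1 ATP-grasp pool
  expect_identical(reactions_of_domain(net, "SucC1"), c("R15", "R23", "R24"))
  # regulatory site attached to no step
  expect_identical(reactions_of_domain(net, "PdhB2"), character(0))
  # annotated enzyme without any step in the printed network
  expect_identical(reactions_of_domain(net, "citZ"), character(0))
  expect_error(reactions_of_domain(net, "NoSuchDomain"), "unknown domain")
})

test_that("inhibition partitions the mode set and reports lost capabilities", {
  fx <- fixture("tca_domain")
  efms <- enumerate_efms(fx$network)

  rep <- inhibit(fx$network, efms, "R5")
  expect_length(rep$removed_modes, 5L)
  expect_length(rep$surviving_modes, 1L)
  expect_true("ATP" %in% rep$lost_capabilities)
  # partition property
  expect_identical(sort(c(rep$removed_modes, rep$surviving_modes)),
                   seq_along(efms$modes))
  expect_length(intersect(rep$removed_modes, rep$surviving_modes), 0L)

  # inhibiting the NAD/FAD-binding domain resolves to the same reactions
  repd <- inhibit(fx$network, efms, "PdhD2")
  expect_identical(repd$target_reactions, c("R5", "R6", "R7"))
  expect_identical(repd$removed_modes, rep$removed_modes)

  # a target hitting no mode leaves the set untouched
  cl <- fixture("tca_classical")
  ecl <- enumerate_efms(cl$network)
  rep0 <- inhibit(cl$network, ecl, "citB")
  expect_true(all(vapply(efm_listing(ecl)[rep0$surviving_modes], nzchar,
                         logical(1))))
  expect_error(inhibit(cl$network, ecl, "R99"), "resolve")

  # exhaustiveness: partition holds for every single-reaction target
  for (rid in names(cl$network$reactions)) {
    r <- inhibit(cl$network, ecl, rid)
    expect_identical(sort(c(r$removed_modes, r$surviving_modes)),
                     seq_along(ecl$modes))
  }
})

test_that("producing_modes filters on the sign of the overall coefficient", {
  ecl <- enumerate_efms(fixture("tca_classical")$network)
  expect_length(producing_modes(ecl, "ATP", "produce"), 2L)
  # the anaplerotic futile cycle consumes ATP
  expect_true(length(producing_modes(ecl, "ATP", "consume")) >= 1L)
  echain <- enumerate_efms(chain_network())
  expect_length(producing_modes(echain, "Cext", "consume"), 0L)
  expect_error(producing_modes(ecl, "Mal"), "internal")
  expect_error(producing_modes(ecl, "nope"), "unknown")
})

test_that("representation comparison is a bijection on the TCA fixtures and symmetric", {
  ecl <- enumerate_efms(fixture("tca_classical")$network)
  edm <- enumerate_efms(fixture("tca_domain")$network)
  cmp <- compare_representations(ecl, edm)
  expect_identical(nrow(cmp$matches), 6L)
  expect_length(cmp$unmatched_classical, 0L)
  expect_length(cmp$unmatched_domain, 0L)
  # reversing the arguments inverts the mapping
  rev_cmp <- compare_representations(edm, ecl)
  expect_identical(
    cmp$matches[order(cmp$matches$classical), c("classical", "domain")],
    data.frame(classical = rev_cmp$matches$domain,
               domain = rev_cmp$matches$classical)[
                 order(rev_cmp$matches$domain), ],
    ignore_attr = TRUE)
  # identity on itself
  self <- compare_representations(ecl, ecl)
  expect_identical(self$matches$classical, self$matches$domain)
  # disjoint toy networks: everything unmatched, nothing raised
  e1 <- enumerate_efms(chain_network())
  e2 <- enumerate_efms(two_route_network())
  dis <- compare_representations(e1, e2)
  expect_identical(nrow(dis$matches), 1L)   # same Aext -> Cext overall
  # an alias table reconciles differently named external vocabularies
  renamed <- build_network(
    list(metabolite("Glc_ex", external = TRUE), metabolite("B"),
         metabolite("Cext", external = TRUE)),
    list(reaction("R1", c(Glc_ex = -1, B = 1)),
         reaction("R2", c(B = -1, Cext = 1))))
  er <- enumerate_efms(renamed)
  expect_identical(nrow(compare_representations(e1, er)$matches), 0L)
  expect_identical(
    nrow(compare_representations(e1, er, aliases = c(Glc_ex = "Aext"))$matches),
    1L)
})
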