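test_that("forced topologies enumerate exactly their obvious modes", {
  e <- enumerate_efms(chain_network())
  expect_length(e$modes, 1L)
  expect_identical(unname(e$modes[[1]]$coeffs), c(1, 1))

  # two parallel irreversible routes -> two modes
  e2 <- enumerate_efms(two_route_network())
  expect_identical(support_keys(e2), c("Ra1 Ra2", "Rb1 Rb2"))

  # an isolated internal reversible pair admits no steady-state flux:
  # the forward+backward two-cycle must not be reported
  expect_length(enumerate_efms(rev_pair_network())$modes, 0L)

  # empty network
  empty <- build_network(list(), list())
  expect_length(enumerate_efms(empty)$modes, 0L)
})

test_that("a reversible-only mode is reported once, oriented positive on its first support entry", {
  # A <-> B with exchange on both: the through mode is reversible end to end
  net <- build_network(
    list(metabolite("Aext", external = TRUE), metabolite("B"),
         metabolite("Cext", external = TRUE)),
    list(reaction("R1", c(Aext = -1, B = 1), reversible = TRUE),
         reaction("R2", c(B = -1, Cext = 1), reversible = TRUE)))
  e <- enumerate_efms(net)
  expect_length(e$modes, 1L)
  expect_identical(unname(e$modes[[1]]$coeffs), c(1, 1))
  # entered backwards, canonicalize flips to positive leading flux
  v <- canonicalize(c(R1 = -2, R2 = -2), net)
  expect_identical(unname(v), c(1, 1))
})

test_that("canonicalize scales to coprime integers and rejects zero", {
  net <- chain_network()
  expect_identical(canonicalize(c(R1 = 0.5, R2 = 0.5), net),
                   canonicalize(c(R1 = 7, R2 = 7), net))
  expect_error(canonicalize(c(R1 = 0, R2 = 0), net), "zero vector")
})

test_that("is_elementary accepts true modes and rejects composites, zero and infeasible vectors", {
  fx <- fixture("tca_classical")
  net <- fx$network
  expect_false(is_elementary(rep(0, 13), net))

  # Table row: the anaplerotic/malic futile cycle
  v1 <- c(pyc = 1, mdh = -1, ywka = 1)
  expect_true(is_elementary(v1, net))

  efms <- enumerate_efms(net)
  for (m in efms$modes) expect_true(is_elementary(m$coeffs, net))

  # sum of two support-disjoint modes balances but is not support-minimal
  csum <- c(pyc = 1, mdh = -1, ywka = 1, pdh = 1, Glyco = 1, Pta = 1)
  expect_false(is_elementary(csum, net))

  # whereas summing the AcP-fed cycle with the AcP-producing branch cancels
  # the acetyl-phosphate shuttle exactly and lands on another mode
  lm <- fixture("tca_classical")$efm_label_map
  vec_of <- function(lab) {
    key <- paste(sort(lm[[lab]]), collapse = " ")
    for (m in efms$modes) {
      if (paste(sort(m$support), collapse = " ") == key) return(m$coeffs)
    }
    stop("label not found")
  }
  expect_true(is_elementary(vec_of("EFM 2") + vec_of("EFM 4"), net))

  # negative flux through an irreversible reaction is not a mode
  expect_false(is_elementary(c(pyc = -1, mdh = 1, ywka = -1), net))
})

test_that("brute-force oracle agrees on the classical TCA network and guards its size", {
  net <- fixture("tca_classical")$network
  expect_identical(support_keys(brute_force_efms(net)),
                   support_keys(enumerate_efms(net)))
  expect_error(brute_force_efms(fixture("tca_domain")$network), "refused")
})

test_that("mode listings render coefficients and direction markers", {
  efms <- enumerate_efms(fixture("tca_domain")$network)
  listing <- efm_listing(efms)
  expect_length(listing, 6L)
  expect_true(any(grepl("\\(2 R5\\)", listing)))
  expect_true(any(grepl("-R25", listing)))
  rep <- efm_report(efms)
  expect_identical(rep$n_modes, 6L)
  expect_named(rep$modes[[1]], c("label", "coefficients", "support", "overall"))
})
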