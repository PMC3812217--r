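# Property-style checks under fixed seeds: enumeration vs brute force,
# exact conservation, elementarity, knockout semantics, split/merge.

test_that("double description and brute force agree on 200 seeded random networks", {
  for (s in 1:200) {
    net <- random_case(s)
    a <- support_keys(enumerate_efms(net))
    b <- support_keys(brute_force_efms(net))
    expect_identical(a, b, info = sprintf("seed %d", s))
  }
})

test_that("every enumerated mode conserves internal metabolites exactly and is elementary", {
  nets <- c(lapply(c(3, 57, 101, 160), random_case),
            list(fixture("tca_classical")$network,
                 fixture("pdh_domain")$network,
                 fixture("tca_domain")$network))
  for (net in nets) {
    S <- stoichiometric_matrix(net)
    efms <- enumerate_efms(net)
    for (m in efms$modes) {
      resid <- as.vector(S %*% m$coeffs)
      expect_true(all(resid == 0))           # exact, not near-zero
      expect_true(is_elementary(m$coeffs, net))
      expect_identical(m$coeffs, canonicalize(m$coeffs, net))
    }
  }
})

test_that("knockout by support filtering equals knockout by re-enumeration", {
  nets <- c(list(fixture("tca_classical")$network,
                 fixture("pdh_domain")$network,
                 fixture("tca_domain")$network),
            lapply(c(11, 72, 133), random_case))
  for (net in nets) {
    efms <- enumerate_efms(net)
    for (rid in names(net$reactions)) {
      filtered <- sort(vapply(
        Filter(function(m) !(rid %in% sub("^-", "", m$support)), efms$modes),
        function(m) paste(sort(m$support), collapse = " "), character(1)))
      reenum <- support_keys(enumerate_efms(drop_reactions(net, rid)))
      expect_identical(reenum, filtered,
                       info = sprintf("%s minus %s", net$id, rid))
    }
  }
})

test_that("splitting reversible reactions and re-merging leaves the canonical EFM set unchanged", {
  nets <- list(fixture("tca_classical")$network,
               random_case(29), random_case(88))
  for (net in nets) {
    split <- split_reversibles(net)
    merged <- character(0)
    for (m in enumerate_efms(split)$modes) {
      v <- merge_split_mode(m$coeffs, net)
      if (all(v == 0)) next                  # futile two-cycle of a split pair
      v <- canonicalize(v, net)
      ss <- ifelse(v[v != 0] > 0, names(v)[v != 0],
                   paste0("-", names(v)[v != 0]))
      merged <- c(merged, paste(sort(ss), collapse = " "))
    }
    expect_identical(sort(unique(merged)), support_keys(enumerate_efms(net)))
  }
})

test_that("random networks are reproducible, valid and size-guarded", {
  a <- random_network(4, 6, 0.5, seed = 42)
  b <- random_network(4, 6, 0.5, seed = 42)
  expect_identical(paste(write_metatool(a), collapse = "\n"),
                   paste(write_metatool(b), collapse = "\n"))
  expect_false(identical(paste(write_metatool(a), collapse = "\n"),
                         paste(write_metatool(random_network(4, 6, 0.5, seed = 43)),
                               collapse = "\n")))
  expect_error(random_network(4, 0), "n_reactions")
  expect_error(random_network(20, 5), "infeasible")
  # generation leaves the global RNG stream untouched
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(random_network(3, 4, seed = 99)); after <- runif(1)
  expect_identical(before, after)
})
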