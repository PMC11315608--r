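test_that("a toy community model parses with the document's counts", {
  b <- makeFixtureBundle(2, 1, 1, 0, seed = 1)
  expect_s4_class(b$model, "CommunityModel")
  expect_identical(members(b$model), c("alpha", "beta"))
  expect_identical(sharedCompartment(b$model), "medium")
  counts <- oracleCountsFromSBML(b$fx$sbml_path)
  expect_identical(nrow(speciesTable(b$model)), counts$n_species)
  expect_identical(nrow(reactionTable(b$model)), counts$n_reactions)
  # re-reading yields an identical model (parsing does not mutate the file)
  again <- readCommunitySBML(b$fx$sbml_path)
  expect_equal(again, b$model)
})

test_that("single-member models parse as degenerate communities", {
  d <- withr::local_tempdir()
  fx <- generateToyCommunity(
    fixtureSpec(1, 1, 0, 0, seed = 3, member_names = "solo"), d)
  m <- readCommunitySBML(fx$sbml_path)
  expect_identical(members(m), "solo")
})

test_that("shared compartment detection honours the SBML parameter", {
  d <- withr::local_tempdir()
  fx <- generateToyCommunity(
    fixtureSpec(2, 1, 0, 0, seed = 1, shared_compartment = "env"), d)
  expect_identical(detectSharedCompartment(fx$sbml_path), "env")
  m <- readCommunitySBML(fx$sbml_path)
  expect_identical(sharedCompartment(m), "env")

  fx2 <- generateToyCommunity(fixtureSpec(2, 1, 0, 0, seed = 1), d)
  expect_identical(detectSharedCompartment(fx2$sbml_path), "medium")

  # neither parameter nor a 'medium' compartment -> convention error
  txt <- readLines(fx2$sbml_path)
  txt <- gsub("\"medium\"", "\"broth\"", txt, fixed = TRUE)
  bad <- file.path(d, "no_medium.xml")
  writeLines(txt, bad)
  expect_error(detectSharedCompartment(bad),
               class = "communet_convention_error")
})

test_that("malformed SBML raises a parse error", {
  d <- withr::local_tempdir()
  bad <- file.path(d, "broken.xml")
  writeLines("<sbml><model>", bad)
  expect_error(readCommunitySBML(bad), class = "communet_parse_error")
  expect_error(readCommunitySBML(file.path(d, "absent.xml")),
               class = "communet_parse_error")
})

test_that("member inference handles plain and underscored member IDs", {
  expect_identical(
    inferMembers(c("a_c", "a_e", "b_c", "medium"), character(), "medium"),
    c("a", "b"))
  # members that themselves contain underscores
  expect_identical(
    inferMembers(c("m_x_c", "m_y_c", "medium"),
                 c("m_x_glc__D_c"), "medium"),
    c("m_x", "m_y"))
  # a long compartment suffix merges into an existing member
  expect_identical(
    inferMembers(c("alpha_c", "alpha_e", "alpha_c_special", "medium"),
                 character(), "medium"),
    "alpha")
  # no members at all
  expect_error(inferMembers("medium", character(), "medium"),
               class = "communet_convention_error")
  # order independence
  expect_identical(
    inferMembers(c("b_c", "medium", "a_e", "a_c"), character(), "medium"),
    inferMembers(c("a_c", "a_e", "b_c", "medium"), character(), "medium"))
})

test_that("flux TSV parsing is header-name based and validating", {
  d <- withr::local_tempdir()
  f <- file.path(d, "flux.tsv")
  writeLines(c("reaction_id\tflux", "R1\t2.5", "R2\t-1.0"), f)
  expect_equal(readFluxTSV(f), c(R1 = 2.5, R2 = -1.0))

  writeLines(c("flux\treaction_id", "2.5\tR1", "-1.0\tR2"), f)
  expect_equal(readFluxTSV(f), c(R1 = 2.5, R2 = -1.0))

  writeLines(c("reaction\tflux", "R1\t2.5"), f)
  expect_error(readFluxTSV(f), class = "communet_format_error")

  writeLines(c("reaction_id\tflux", "R1\t2.5", "R1\t1"), f)
  expect_error(readFluxTSV(f), class = "communet_format_error")

  writeLines(c("reaction_id\tflux", "R1\ttwo"), f)
  expect_error(readFluxTSV(f), class = "communet_format_error")

  writeLines(c("reaction_id\tflux\tnote", "R1\t1\thello"), f)
  expect_warning(v <- readFluxTSV(f), "extra column")
  expect_equal(v, c(R1 = 1))
})

test_that("FVA TSV parsing enforces min <= max and allows empty tables", {
  d <- withr::local_tempdir()
  f <- file.path(d, "fva.tsv")
  writeLines(c("reaction_id\tmin_flux\tmax_flux", "R1\t-3\t5"), f)
  rg <- readFVATSV(f)
  expect_equal(rg$min_flux, -3)
  expect_equal(rg$max_flux, 5)

  writeLines(c("reaction_id\tmin_flux\tmax_flux", "R1\t2\t1"), f)
  expect_error(readFVATSV(f), class = "communet_format_error")

  writeLines("reaction_id\tmin_flux\tmax_flux", f)
  expect_identical(nrow(readFVATSV(f)), 0L)
})

test_that("transport collection classifies members, boundaries and rejects
           multi-metabolite transporters", {
  b <- makeFixtureBundle(3, 1, 1, 1, seed = 5)
  tr <- b$transports
  # canonical secretion transporter
  one <- tr[tr$reaction_id == "TR_alpha_privalpha1", ]
  expect_identical(one$member, "alpha")
  expect_identical(one$external_species, "privalpha1_medium")
  expect_equal(one$external_coefficient, 1)
  # boundary exchange -> SHARED sentinel
  ex <- tr[tr$reaction_id == "EX_core1", ]
  expect_identical(ex$member, SHARED_MEMBER)
  expect_equal(ex$external_coefficient, -1)
  # internal SRC reactions never appear
  expect_false(any(grepl("^SRC_", tr$reaction_id)))

  # a reaction with two shared-compartment species is excluded with warning
  m <- b$model
  extra <- m@reactions[1, ]
  extra$reaction_id <- "BAD_two_medium"
  extra$stoichiometry <- list(c(privalpha1_medium = -1, core1_medium = 1))
  m@reactions <- rbind(m@reactions, extra)
  expect_warning(tr2 <- collectTransportReactions(m), "excluded")
  expect_false("BAD_two_medium" %in% tr2$reaction_id)
  expect_setequal(tr2$reaction_id, tr$reaction_id)

  # a reaction joining two members' species is a convention error
  m2 <- b$model
  bad <- m2@reactions[1, ]
  bad$reaction_id <- "BAD_two_members"
  bad$stoichiometry <- list(c(alpha_core1_c = -1, beta_core1_c = -1,
                              core1_medium = 2))
  m2@reactions <- rbind(m2@reactions, bad)
  expect_error(collectTransportReactions(m2),
               class = "communet_convention_error")
})

test_that("missing FBC bounds fall back to defaults with a warning", {
  b <- makeFixtureBundle(2, 1, 0, 0, seed = 2)
  txt <- readLines(b$fx$sbml_path)
  txt <- gsub(" fbc:lowerFluxBound=\"cm_lb\" fbc:upperFluxBound=\"cm_ub\"",
              "", txt, fixed = TRUE)
  f <- file.path(b$dir, "nobounds.xml")
  writeLines(txt, f)
  expect_warning(m <- readCommunitySBML(f), "default")
  expect_equal(unique(reactionTable(m)$lower_bound), -1000)
  expect_equal(unique(reactionTable(m)$upper_bound), 1000)
})
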