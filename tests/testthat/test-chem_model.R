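# Molecule container, force-field serialization and parameter assignment.

test_that("molecule validates topology and conformers", {
  expect_error(molecule(c(6L, 6L), rbind(c(1, 3, 1))), "out of atom range")
  expect_error(molecule(c(6L, 6L), rbind(c(1, 2, 1), c(2, 1, 1))),
               "duplicate")
  expect_error(molecule(c(6L, 6L), rbind(c(1, 2, 1)),
                        conformers = matrix(0, 3, 3)), "N x 3")
  expect_error(molecule(c(6L, 6L), rbind(c(1, 2, 1)), charges = 0.1),
               "charge count")
  m <- molecule(c(6L, 6L), rbind(c(2, 1, 1)))
  expect_equal(m$bonds[1, 1:2], c(i = 1L, j = 2L))  # normalized order
})

test_that("SDF round trip preserves topology, conformers and charges", {
  m <- toy_mols$alcohol
  path <- withr::local_tempfile(fileext = ".sdf")
  write_molecules_sdf(m, path)
  back <- read_molecules_sdf(path)[[1]]
  expect_equal(back$elements, m$elements)
  expect_equal(back$bonds, m$bonds)
  expect_equal(back$conformers[[1]], m$conformers[[1]], tolerance = 1e-3)
  expect_equal(back$charges, m$charges, tolerance = 1e-8)
  # multi-conformer records merge back into one molecule
  m2 <- m; m2$conformers <- list(m$conformers[[1]], m$conformers[[1]] + 0.1)
  write_molecules_sdf(m2, path)
  back2 <- read_molecules_sdf(path)
  expect_length(back2, 1)
  expect_length(back2[[1]]$conformers, 2)
})

test_that("force-field serialization round-trips in both dialects", {
  ff <- toy_ff
  for (fmt in c("xml", "json")) {
    txt <- serialize_forcefield(ff, fmt)
    back <- parse_forcefield(txt)
    expect_equal(back$parameters, ff$parameters)
    expect_equal(back$scale14_vdw, ff$scale14_vdw)
    expect_equal(back$scale14_elec, ff$scale14_elec)
    # parse -> serialize -> parse is the identity on the data model
    expect_equal(parse_forcefield(serialize_forcefield(back, fmt)),
                 back)
  }
})

test_that("force-field list order and unknown sections survive round trip", {
  xml <- paste0(
    '<ForceField name="t" version="1">',
    '<Bonds>',
    '<Bond id="b1" smirks="[#6:1]-[#6:2]" k="500" length="1.5"/>',
    '<Bond id="b2" smirks="[#6X4:1]-[#6X4:2]" k="510" length="1.52"/>',
    '</Bonds>',
    '<FutureSection answer="42">kept verbatim</FutureSection>',
    '</ForceField>')
  ff <- parse_forcefield(xml)
  ids <- vapply(ff$parameters$bond, function(p) p$id, character(1))
  expect_equal(ids, c("b1", "b2"))
  expect_match(ff$extras, "FutureSection")
  back <- parse_forcefield(serialize_forcefield(ff))
  expect_equal(vapply(back$parameters$bond, function(p) p$id, character(1)),
               c("b1", "b2"))
  expect_equal(back$extras, ff$extras)
})

test_that("malformed parameters are rejected with informative errors", {
  expect_error(smirks_parameter("bx", "[#6:1]-[#6:2]-[#6:3]", "bond",
                                k = 1, length = 1), "3 tagged")
  expect_error(smirks_parameter("nx", "[#6:1]", "vdw", epsilon = -1,
                                rmin_half = 1), "epsilon")
  expect_error(smirks_parameter("nx", "[#6:1]", "vdw", epsilon = 1,
                                rmin_half = 0), "rmin_half")
  expect_error(smirks_parameter("tx", "[*:1]~[*:2]~[*:3]~[*:4]",
                                "proper_torsion", k = 1, periodicity = 0,
                                phase = 0), "positive")
  expect_error(forcefield(list(bond = list(
    smirks_parameter("b1", "[*:1]~[*:2]", "bond", k = 1, length = 1),
    smirks_parameter("b1", "[#6:1]~[#6:2]", "bond", k = 1, length = 1)))),
    "duplicate")
  expect_error(smarts_parse("[#6:1]1CC1"), "ring-closure")
})

test_that("canonical keys collapse symmetric tuples", {
  expect_equal(canonical_key(c(5, 2), "bond"), c(2L, 5L))
  expect_equal(canonical_key(c(4, 1, 2), "angle"), c(2L, 1L, 4L))
  expect_equal(canonical_key(c(3, 2, 1, 0), "proper_torsion"),
               canonical_key(c(0, 1, 2, 3), "proper_torsion"))
  expect_equal(canonical_key(c(7, 4, 9, 2), "improper_torsion"),
               c(4L, 2L, 7L, 9L))
  expect_error(canonical_key(c(1, 2, 3), "bond"), "length")
})

test_that("SMARTS matcher agrees with an independent reference engine", {
  # expected tuples computed with RDKit 2024.09.2 GetSubstructMatches on
  # the same molecules (tagged-atom columns, 1-based)
  oracle <- list(
    list("alkane4", "[#6X4:1]-[#6X4:2]",
         "1,2;2,1;2,3;3,2;3,4;4,3"),
    list("alkane4", "[#1:1]-[#6X4]", "5;6;7;8;9;10;11;12;13;14"),
    list("alcohol", "[#1:1]-[#8]", "4"),
    list("alcohol", "[#8X2H1+0:1]", "3"),
    list("alcohol", "[*:1]~[#6X4:2]-[#8X2:3]~[*:4]",
         "1,2,3,4;8,2,3,4;9,2,3,4"),
    list("amide", "[*:1]~[#6X3:2](~[*:3])~[*:4]",
         "1,2,3,4;1,2,4,3;3,2,1,4;3,2,4,1;4,2,1,3;4,2,3,1"),
    list("amide", "[#6X3:1]-[#7:2]", "2,4"),
    list("amide", "[#1:1]-[#6X3]", ""),
    list("sulfonamide", "[#16:1]=[#8:2]", "2,3;2,4"),
    list("nitrile", "[#6:1]#[#7:2]", "2,3"),
    list("glycol", "[#8:1]-[#1:2]", "1,5;4,6")
  )
  for (case in oracle) {
    m <- toy_mols[[case[[1]]]]
    got <- smarts_matches(m, case[[2]])
    got_str <- if (nrow(got) == 0) "" else
      paste(sort(apply(got, 1, paste, collapse = ",")), collapse = ";")
    exp_str <- if (case[[3]] == "") "" else
      paste(sort(strsplit(case[[3]], ";")[[1]]), collapse = ";")
    expect_equal(got_str, exp_str,
                 label = paste(case[[1]], case[[2]]))
  }
})

test_that("assignment is last-match-wins, deterministic and complete", {
  m <- toy_mols$alkane4
  asg <- assign_parameters(m, toy_ff)
  # ethane-like C-C bonds: generic b1 is overridden by tetravalent b2
  cc <- asg$by_class$bond[["1-2"]]
  expect_equal(cc$id, "b2")
  # appending a copy of b2 under a new id at the end reassigns its tuples
  ff2 <- toy_ff
  p <- ff_get_parameter(ff2, "bond", "b2")
  p$id <- "b99"
  ff2$parameters$bond <- c(ff2$parameters$bond, list(p))
  asg2 <- assign_parameters(m, ff2)
  expect_equal(asg2$by_class$bond[["1-2"]]$id, "b99")
  # determinism: byte-identical serialized assignments
  expect_identical(serialize(asg, NULL), serialize(assign_parameters(m, toy_ff), NULL))
})

test_that("hydroxyl hydrogen receives the hydrogen-on-oxygen vdW type", {
  asg <- assign_parameters(toy_mols$alcohol, toy_ff)
  expect_equal(asg$by_class$vdw[["4"]]$id, "n2")  # atom 4 = hydroxyl H
})

test_that("parameters matching no chemistry apply to zero tuples", {
  # alkane has no nitrogen: nitrogen vdW type n8 is never assigned
  asg <- assign_parameters(toy_mols$alkane4, toy_ff)
  expect_false("n8" %in% assigned_ids(asg))
})

test_that("unassigned chemistry raises an error naming the tuple", {
  ff_gap <- forcefield(list(
    bond = list(smirks_parameter("b", "[#7:1]~[#7:2]", "bond", k = 1,
                                 length = 1)),
    angle = list(smirks_parameter("a", "[*:1]~[*:2]~[*:3]", "angle",
                                  k = 0, angle = 109.5)),
    proper_torsion = list(smirks_parameter("t", "[*:1]~[*:2]~[*:3]~[*:4]",
                                           "proper_torsion", k = 0,
                                           periodicity = 3, phase = 0)),
    vdw = list(smirks_parameter("n", "[*:1]", "vdw", epsilon = 0,
                                rmin_half = 1))))
  expect_error(assign_parameters(diatomic(), ff_gap), "unassigned")
})

test_that("applied parameter counts count molecules, not tuples", {
  m <- toy_mols$alkane4
  five <- stats::setNames(rep(list(m), 5), paste0("c", 1:5))
  counts <- applied_parameter_counts(five, toy_ff)
  used <- counts[counts > 0]
  expect_true(all(used == 5))
  expect_true(all(applied_parameter_counts(list(), toy_ff) == 0))
  # cross-check one id against exhaustive per-molecule matching
  n_with_b2 <- sum(vapply(toy_mols, function(mm)
    nrow(smarts_matches(mm, "[#6X4:1]-[#6X4:2]")) > 0, logical(1)))
  expect_equal(unname(applied_parameter_counts(toy_mols, toy_ff)["b2"]),
               n_with_b2)
})
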