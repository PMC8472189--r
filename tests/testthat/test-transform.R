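test_that("plant degradation opens the less-chlorinated ring", {
  expect_identical(plant_degrade(3)$name, "4-CBA")
  expect_identical(plant_degrade(31)$name, "2,5-CBA")
  expect_identical(plant_degrade(0)$name, "benzoic acid")
  # tie in ring chlorine counts: both outcomes, deduplicated
  expect_identical(plant_degrade(4)$name, "2-CBA")    # 2,2' -> one acid
  expect_setequal(plant_degrade(52)$name, "2,5-CBA")  # symmetric rings
  expect_setequal(plant_degrade(congener("25", "34"))$name,
                  c("2,5-CBA", "3,4-CBA"))
})

test_that("aerobic hydroxylation adds OH at free meta/para sites only", {
  p107 <- aerobic_hydroxylate(107)
  expect_true("4-OH-CB107" %in% p107$name)
  expect_true(all(p107$site_class %in% c("meta", "para")))
  expect_true(p107$preferred[p107$name == "4-OH-CB107"])
  p153 <- aerobic_hydroxylate(153)
  expect_true("3-OH-CB153" %in% p153$name)
  expect_identical(nrow(aerobic_hydroxylate(209)), 0L)
  # chlorine count is preserved
  expect_identical(count_cl(product_smiles(p107)), rep(congener(107)$n_cl, nrow(p107)))
})

test_that("anaerobic dechlorination removes exactly one chlorine", {
  p101 <- anaerobic_dechlorinate(101)
  expect_true("PCB-49" %in% p101$name)
  p90 <- anaerobic_dechlorinate(90)
  expect_true(all(c("PCB-49", "PCB-68") %in% p90$name))
  # the ortho route (PCB-68) must not be flagged as a preferred main site
  expect_false(p90$preferred[p90$name == "PCB-68"])
  expect_true(p90$preferred[p90$name == "PCB-49"])
  expect_identical(nrow(anaerobic_dechlorinate(0)), 0L)
  for (i in seq_len(nrow(p90)))
    expect_identical(congener(p90$product_number[i])$n_cl, congener(90)$n_cl - 1L)
})

test_that("biometabolism adds MeSO2 at free meta/para sites", {
  expect_true("3'-MeSO2-CB49" %in% biometabolize(49)$name)
  p174 <- biometabolize(174)
  expect_true("4-MeSO2-CB174" %in% c(p174$name, p174$alias))
  expect_identical(nrow(biometabolize(209)), 0L)
  # the renumbering gives the added group, not the chlorines, the low locant
  expect_true("3-MeSO2-CB110" %in% biometabolize(110)$name)
})

test_that("photodechlorination reaches the expected congeners", {
  expect_true(15 %in% photodechlorinate(47, 2)$product_number)
  expect_true(11 %in% photodechlorinate(40, 2)$product_number)
  expect_true(70 %in% photodechlorinate(101, 1)$product_number)
  p <- photodechlorinate(171, 4)
  expect_true(35 %in% p$product_number)
  expect_identical(p$steps[p$product_number == 35], 4L)
  # with max_steps = n_cl the fully dechlorinated biphenyl is reached
  expect_true(0 %in% photodechlorinate(52, congener(52)$n_cl)$product_number)
  # minimal step counts: a single removal is never reported with steps > 1
  p1 <- photodechlorinate(52, 3)
  one_off <- p1$product_number[vapply(p1$product_number, function(n)
    congener(n)$n_cl == 3L, logical(1))]
  expect_true(all(p1$steps[p1$product_number %in% one_off] == 1L))
  expect_error(photodechlorinate(52, 0))
})

test_that("product sets are invariant under symmetry-equivalent input", {
  for (cg in gen_congeners(15, seed = 42)) {
    if (cg$n_cl == 0L) next
    # feed the flipped/swapped raw patterns instead of the canonical form
    alt <- congener(pcbtrans:::flip_ring(cg$ring_b), pcbtrans:::flip_ring(cg$ring_a))
    expect_identical(alt$number, cg$number)
    for (pw in c("plant", "microbial_aerobic", "microbial_anaerobic", "biometabolism"))
      expect_identical(transform_products(cg, pw), transform_products(alt, pw))
  }
})

test_that("generated PCB products are always valid congener numbers", {
  for (cg in gen_congeners(20, seed = 7)) {
    if (cg$n_cl == 0L) next
    nums <- c(anaerobic_dechlorinate(cg)$product_number,
              photodechlorinate(cg, min(cg$n_cl, 3L))$product_number)
    expect_true(all(nums %in% 0:209))
  }
})

test_that("mapping verification flags wrong products and unknown parents", {
  bad <- data.frame(row = 1L, pathway = "plant", parent = "PCB-3",
                    products = "2-CBA", stringsAsFactors = FALSE)
  expect_false(verify_product_mappings(bad)$matched)
  expect_identical(nrow(verify_product_mappings(bad[0, ])), 0L)
  unk <- data.frame(row = 1L, pathway = "plant", parent = "Aroclor-1254",
                    products = "2-CBA", stringsAsFactors = FALSE)
  expect_error(verify_product_mappings(unk), "unknown parent")
})
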