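base <- normal_labs()
above <- week_summary(150, 95)
near <- week_summary(135, 70)

engine <- function(regimen, ws = above, profile = std_profile(),
                   pathway = std_pathway(), labs = base, screen = NULL,
                   as_of = DECISION_DATE, ...) {
  next_action(profile, pathway, regimen, ws$summary, ws$goal,
              labs = labs, baseline_labs = base, as_of = as_of,
              secondary_screen = screen, ...)
}

test_that("pathway assignment: childbearing outranks RAAS-first", {
  male <- std_profile(sex = "male")
  expect_equal(assign_pathway(male, base)$pathway, "STANDARD")
  ckd <- normal_labs(egfr = 50)
  f60 <- std_profile(age = 60, sex = "female", contraception = FALSE)
  expect_equal(assign_pathway(f60, ckd)$pathway, "RAAS_FIRST")
  expect_equal(assign_pathway(std_profile(diabetes = TRUE), base)$pathway,
               "RAAS_FIRST")
  expect_equal(assign_pathway(male, normal_labs(uacr = 35))$pathway,
               "RAAS_FIRST")
  # a 40-year-old diabetic woman without contraception: childbearing wins
  f40 <- std_profile(age = 40, sex = "female", contraception = FALSE,
                     diabetes = TRUE)
  expect_equal(assign_pathway(f40, base)$pathway, "CHILDBEARING")
  # with contraception she is not of childbearing potential
  f40c <- std_profile(age = 40, sex = "female", contraception = TRUE,
                      diabetes = TRUE)
  expect_equal(assign_pathway(f40c, base)$pathway, "RAAS_FIRST")
  # missing UACR is treated as below threshold, with a warning
  expect_warning(pw <- assign_pathway(male, normal_labs(uacr = NA)), "UACR")
  expect_equal(pw$pathway, "STANDARD")
})

test_that("RAAS agent selection: potent-ARB policy", {
  sel <- select_raas_agent(list())
  expect_equal(sel[c("agent", "action")], list(agent = "irbesartan",
                                               action = "START"))
  sw <- select_raas_agent(list(med("losartan", 2)))
  expect_equal(sw$action, "SWITCH")
  expect_equal(sw$agent, "irbesartan")
  # lisinopril titrates in place per protocol
  ti <- select_raas_agent(list(med("lisinopril", 1)))
  expect_equal(ti[c("agent", "action")], list(agent = "lisinopril",
                                              action = "TITRATE"))
  expect_equal(ti$target_dose_step, 2)
  # potent ARB at max: slot exhausted
  expect_null(select_raas_agent(list(med("irbesartan", 3))))
  expect_error(select_raas_agent(list(med("irbesartan", 1),
                                      med("lisinopril", 1))),
               "both ARB and ACEI")
})

test_that("engine: first line, maximize before add, class sequencing", {
  # naive standard-pathway patient starts a CCB
  rec <- engine(list(), profile = std_profile(medication_naive = TRUE))
  expect_equal(rec$action, "START")
  expect_equal(rec$agent, "amlodipine")
  expect_false(rec$requires_lab_gate)
  # CCB below max: titrate, never add
  rec2 <- engine(list(med("amlodipine", 2)))
  expect_equal(rec2$action, "TITRATE")
  expect_equal(rec2$target_dose_step, 3)
  # CCB at max: add the ARB (RAAS second line on the standard pathway)
  rec3 <- engine(list(med("amlodipine", 3)))
  expect_equal(rec3$action, "ADD")
  expect_equal(rec3$agent, "irbesartan")
  expect_true(rec3$requires_lab_gate)
  # CCB intolerant counts as exhausted: move to the ARB
  rec4 <- engine(list(med("amlodipine", 1, intolerant = TRUE)))
  expect_equal(rec4$agent, "irbesartan")
  # RAAS-first pathway starts with the ARB instead
  rec5 <- engine(list(), pathway = std_pathway("RAAS_FIRST"))
  expect_equal(rec5$agent, "irbesartan")
  # third line: thiazide after CCB and ARB are maxed
  rec6 <- engine(list(med("amlodipine", 3), med("irbesartan", 3)))
  expect_equal(rec6$action, "ADD")
  expect_equal(rec6$agent, "hctz")
  # hyponatremia contraindicates the thiazide: skip to secondary screen
  rec7 <- engine(list(med("amlodipine", 3), med("irbesartan", 3)),
                 labs = normal_labs(na = 133, role = "followup"))
  expect_equal(rec7$action, "ORDER_SECONDARY_LABS")
})

test_that("engine: at-goal holds; safety floor and low HR trigger conversation", {
  at_goal <- week_summary(120, 70)
  expect_equal(engine(list(med("amlodipine", 2)), at_goal)$action, "HOLD")
  floor <- week_summary(131, 49)
  expect_equal(engine(list(med("amlodipine", 2)), floor)$action,
               "PHYSICIAN_CONVERSATION")
  # on a beta blocker with weekly mean HR below 55: conversation, no titration
  low_hr <- week_summary(150, 95, hr = 50)
  rec <- engine(list(med("amlodipine", 3), med("labetalol", 1)), low_hr,
                pathway = std_pathway("CHILDBEARING"))
  expect_equal(rec$action, "PHYSICIAN_CONVERSATION")
  expect_true("HR_LT_55_ON_BB" %in% rec$rationale_codes)
})

test_that("engine: titration lockouts of 1 week, 6 weeks for MRA", {
  fresh <- list(med("amlodipine", 2, changed = DECISION_DATE - 3))
  expect_equal(engine(fresh)$action, "HOLD")
  week_old <- list(med("amlodipine", 2, changed = DECISION_DATE - 7))
  expect_equal(engine(week_old)$action, "TITRATE")
  mra5w <- c(max_three_drug(),
             list(med("spironolactone", 1, changed = DECISION_DATE - 35)))
  expect_equal(engine(mra5w, screen = list(reviewed_positive = FALSE))$action,
               "HOLD")
  mra6w <- c(max_three_drug(),
             list(med("spironolactone", 1, changed = DECISION_DATE - 42)))
  rec <- engine(mra6w, screen = list(reviewed_positive = FALSE))
  expect_equal(rec$action, "TITRATE")
  expect_equal(rec$agent, "spironolactone")
})

test_that("engine: lifestyle-first trial for naive stage-1 low-risk patients", {
  naive <- std_profile(medication_naive = TRUE, ascvd_risk_10yr = 0.05)
  stage1 <- week_summary(135, 85)
  expect_equal(engine(list(), stage1, profile = naive)$action, "LIFESTYLE_TRIAL")
  # above the stage-1 band: straight to pharmacotherapy
  expect_equal(engine(list(), above, profile = naive)$action, "START")
  # risk at or above 10%: no lifestyle-only trial
  risky <- std_profile(medication_naive = TRUE, ascvd_risk_10yr = 0.12)
  expect_equal(engine(list(), stage1, profile = risky)$action, "START")
  # unknown risk: no lifestyle-only trial
  unk <- std_profile(medication_naive = TRUE, ascvd_risk_10yr = NA)
  expect_equal(engine(list(), stage1, profile = unk)$action, "START")
})

test_that("engine: chlorthalidone switch inside the 10 mmHg margin", {
  on_max_hctz <- list(med("amlodipine", 3), med("irbesartan", 3),
                      med("hctz", 2))
  rec <- engine(on_max_hctz, near) # 135 vs goal 130: distance 5 < 10
  expect_equal(rec$action, "SWITCH")
  expect_equal(rec$agent, "chlorthalidone")
  far <- week_summary(145, 70) # distance 15: no switch, screen instead
  expect_equal(engine(on_max_hctz, far)$action, "ORDER_SECONDARY_LABS")
})

test_that("engine: secondary screen, fourth line MRA/BB, referral", {
  reg <- max_three_drug()
  expect_equal(engine(reg)$action, "ORDER_SECONDARY_LABS")
  expect_equal(engine(reg, screen = list(reviewed_positive = TRUE))$action,
               "REFER_SPECIALIST")
  # negative screen, potassium permitting: MRA; eplerenone for males
  rec <- engine(reg, screen = list(reviewed_positive = FALSE))
  expect_equal(rec$action, "ADD")
  expect_equal(rec$agent, "eplerenone")
  recf <- engine(reg, screen = list(reviewed_positive = FALSE),
                 profile = std_profile(sex = "female", age = 60))
  expect_equal(recf$agent, "spironolactone")
  # K in the conservative band: MRA added at the conservative start
  rec_k <- engine(reg, screen = list(reviewed_positive = FALSE),
                  labs = normal_labs(k = 4.8, role = "followup"))
  expect_equal(rec_k$agent, "eplerenone")
  expect_equal(rec_k$target_dose_step,
               starting_step("eplerenone", conservative = TRUE))
  # K blocks the MRA: beta blocker instead; metoprolol for reactive airway
  rec_bb <- engine(reg, screen = list(reviewed_positive = FALSE),
                   labs = normal_labs(k = 5.3, role = "followup"))
  expect_equal(rec_bb$agent, "labetalol")
  rec_met <- engine(reg, screen = list(reviewed_positive = FALSE),
                    labs = normal_labs(k = 5.3, role = "followup"),
                    profile = std_profile(reactive_airway = TRUE))
  expect_equal(rec_met$agent, "metoprolol")
  # everything maximized or intolerable: specialist referral
  exhausted <- c(reg, list(med("eplerenone", 2), med("labetalol", 3)))
  expect_equal(engine(exhausted,
                      screen = list(reviewed_positive = FALSE))$action,
               "REFER_SPECIALIST")
})

test_that("engine: childbearing pathway goes CCB then labetalol then referral", {
  pw <- std_pathway("CHILDBEARING")
  young <- std_profile(age = 35, sex = "female")
  expect_equal(engine(list(), profile = young, pathway = pw)$agent,
               "amlodipine")
  rec <- engine(list(med("amlodipine", 3)), profile = young, pathway = pw)
  expect_equal(rec$action, "ADD")
  expect_equal(rec$agent, "labetalol")
  done <- list(med("amlodipine", 3), med("labetalol", 3))
  expect_equal(engine(done, profile = young, pathway = pw)$action,
               "REFER_SPECIALIST")
})

test_that("regimen with two RAAS blockers is rejected", {
  expect_error(engine(list(med("irbesartan", 1), med("lisinopril", 1))),
               "two RAAS")
})

test_that("pandemic mode substitutes lab-free agents or defers to lifestyle", {
  covid <- std_pathway("STANDARD", covid_mode = TRUE)
  # next step would be the ARB; no labs; weekly 145/88 -> CCB ladder first
  ws <- week_summary(145, 88)
  rec <- engine(list(med("amlodipine", 2)), ws, pathway = covid,
                labs_available = FALSE)
  expect_equal(rec$agent, "amlodipine") # still room on the CCB ladder
  rec2 <- engine(list(med("amlodipine", 3)), ws, pathway = covid,
                 labs_available = FALSE)
  expect_equal(rec2$agent, "labetalol")
  expect_false(rec2$requires_lab_gate)
  # below 140/90: lifestyle with 2-month follow-up instead of a lab agent
  mild <- week_summary(135, 85)
  rec3 <- engine(list(med("amlodipine", 3)), mild, pathway = covid,
                 labs_available = FALSE)
  expect_equal(rec3$action, "LIFESTYLE_TRIAL")
  # lab-free next step is unaffected by pandemic mode
  rec4 <- engine(list(med("amlodipine", 1)), ws, pathway = covid,
                 labs_available = FALSE)
  expect_equal(rec4$action, "TITRATE")
  expect_equal(rec4$agent, "amlodipine")
  # labs available but constrained: conservative dosing on new lab-agent starts
  rec5 <- engine(list(med("amlodipine", 3)), ws, pathway = covid,
                 labs_available = TRUE)
  expect_equal(rec5$agent, "irbesartan")
  expect_equal(rec5$target_dose_step,
               starting_step("irbesartan", conservative = TRUE))
  expect_true("COVID_CONSERVATIVE_DOSING" %in% rec5$rationale_codes)
})

test_that("combination pills are offered only once doses are stable", {
  stable <- list(med("irbesartan", 3, changed = "2021-11-01"),
                 med("hctz", 1, changed = "2021-11-01"))
  rec <- consolidate_combo(stable, as_of = DECISION_DATE)
  expect_equal(rec$action, "CONSOLIDATE_COMBO")
  expect_equal(rec$product, "irbesartan/HCTZ")
  # thiazide alone: nothing to combine
  expect_null(consolidate_combo(list(med("hctz", 1)), as_of = DECISION_DATE))
  # mid-titration regimen is not consolidated
  fresh <- list(med("irbesartan", 3, changed = DECISION_DATE - 7),
                med("hctz", 1, changed = "2021-11-01"))
  expect_null(consolidate_combo(fresh, as_of = DECISION_DATE))
})

test_that("applying recommendations updates the regimen correctly", {
  reg <- list()
  rec <- engine(list(), profile = std_profile(medication_naive = TRUE))
  reg <- apply_recommendation(reg, rec, "2022-01-17")
  expect_length(reg, 1)
  expect_equal(reg[[1]]$agent, "amlodipine")
  rec2 <- engine(reg, as_of = as.Date("2022-01-24"))
  reg2 <- apply_recommendation(reg, rec2, "2022-01-24")
  expect_equal(reg2[[1]]$dose_step, reg[[1]]$dose_step + 1)
  # a SWITCH replaces the slot occupant
  reg3 <- apply_recommendation(list(med("hctz", 2)),
                               engine(list(med("amlodipine", 3),
                                           med("irbesartan", 3),
                                           med("hctz", 2)), near),
                               "2022-01-24")
  agents <- vapply(reg3, function(m) m$agent, character(1))
  expect_true("chlorthalidone" %in% agents)
  expect_false("hctz" %in% agents)
})
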