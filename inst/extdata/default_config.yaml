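# Default configuration for the colonoscopy-demand microsimulation.
#
# The person-level registry behind the original program parameters is not
# public; the values below are calibrated stand-ins chosen so that the
# simulated program reproduces the published yearly aggregates of a Spanish
# FIT-based screening program (invitations, participation, positivity,
# colonoscopy uptake and result mix over 2015-2034). All probabilities are
# decimals in [0, 1]; all intervals are integer years. Stratified screening
# fields accept either one shared value or a vector of eight
# (male/female x age groups 50-54, 55-59, 60-64, 65-69).

demography:
  initial_size: 100000          # persons aged 50-69 at simulation start
  age_min: 50.0
  age_max: 70.0                 # initial ages uniform on [age_min, age_max)
  male_share: 0.5
  start_year: 2015
  horizon_years: 20
  # 50-year-old entrants per calendar year, linear between the two anchors
  # (calibrated so yearly invitations grow as published: ~44.6k -> ~58.6k)
  entrants_start: 7000          # entrants in start_year + 1
  entrants_end: 7400            # entrants in the final year
  # Gompertz mortality hazard h(age) = a * exp(b * age), by gender; used to
  # build the piecewise-constant hazard table for time-to-death sampling
  gompertz:
    male:   {a: 1.17e-05, b: 0.104}
    female: {a: 5.2e-06, b: 0.108}

screening:
  ess: 500                      # effective sample size of every Beta prior
  exclusion_initial: 0.039      # before first invitation (all causes)
  exclusion_successive: 0.012    # later rounds, medical reasons only
  opportunistic: 0.043          # reports a colonoscopy within the last 5 years
  opportunistic_recent_share: 0.5  # of those, had it <= 3 years ago (defer 4y)
  participation_initial: 0.438
  participation_prev_participant: 0.815
  participation_prev_nonparticipant: 0.24
  positivity_initial: 0.067     # FIT >= 100 ng hemoglobin / mL
  positivity_successive: 0.0443
  refusal: 0.168                # refuses colonoscopy after a positive FIT
  second_look: 0.123            # repeat colonoscopy within 1 year
  result_initial:               # colonoscopy findings, initial screens
    negative: 0.320
    low_risk: 0.175
    intermediate_risk: 0.275
    high_risk: 0.167
    cancer: 0.063
  result_successive:            # colonoscopy findings, successive screens
    negative: 0.423
    low_risk: 0.203
    intermediate_risk: 0.263
    high_risk: 0.079
    cancer: 0.032
  reinvite:                     # years until the next routine invitation
    non_participation: 2
    negative_fit: 2
    refusal: 2
    low_risk: 2                 # low-risk adenomas return to routine screening
    opportunistic_recent: 4     # outside colonoscopy <= 3 years ago
    opportunistic_old: 2        # outside colonoscopy 3-5 years ago
    negative_colonoscopy: 10    # negative index colonoscopy

surveillance:
  result:                       # findings at surveillance colonoscopies
    negative: 0.715
    low_risk: 0.257
    intermediate_high: 0.025
    cancer: 0.003
  entry_interval:               # years from index finding to first exam
    high_risk: 1
    intermediate_risk: 3
  age_cap: 80                   # no surveillance exam at or beyond this age
  adherence: {min: 0.20, max: 0.90}  # uniform prior, drawn once per run
  on_miss: reschedule           # missed exam is rescheduled one recall
                                # interval later (alternative: exit)
  discharge_negatives: 2        # consecutive negative exams before discharge
                                # back to routine screening (0 = never)
  discharge_interval: 5         # years from discharge to next routine round
  transitions:                  # after an attended exam
    negative:          {action: reschedule, interval: 3}
    low_risk:          {action: reschedule, interval: 3}
    intermediate_high: {action: reschedule, interval: 3}
    cancer:            {action: exit, interval: 0}

psa:
  probabilistic:                # fields given Beta priors (others point mass)
    - exclusion_initial
    - exclusion_successive
    - opportunistic
    - participation_initial
    - participation_prev_participant
    - participation_prev_nonparticipant
    - positivity_initial
    - positivity_successive
    - refusal

run:
  filter:                       # current-scenario run filter (20-year means)
    participation: [0.40, 0.60]
    positivity: [0.047, 0.068]
    adherence: [0.35, 0.70]
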