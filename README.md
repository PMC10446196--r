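# surveyguard

Points-based fraud screening for incentivized online surveys.

Web surveys that pay respondents attract fraud: "professional survey takers"
outside the target population, and bots that auto-complete forms in bulk —
thousands of screener attempts within an hour of launch is a realistic attack.
surveyguard is for study teams running such surveys. It implements:

* a **two-stage eligibility screen** — zip-to-county validation, CAPTCHA and
  speed-bump gates, a honeypot, and client/server time-zone checks that *bar*
  suspicious respondents from ever receiving a survey link;
* a **points-based fraud classifier** — each indicator of possible fraud
  contributes 1 or 2 points (infeasibly short completion < 8 min, duplicate
  hashed IPs, duplicate contact details, unusual email formats, inactive
  recruitment sources, cross-form inconsistencies such as a 5-year-old in 8th
  grade, duplicate or near-duplicate open text, simultaneous county+zip
  matches, identical-response clusters of 3+, wave-patterned submission
  timing, client clocks > 60 min from the server). A record totalling
  **≥ 2 points** is labelled fraudulent; a single 2-point indicator suffices,
  a single 1-point indicator does not;
* a **labelled cohort simulator** — legitimate respondents (completion times
  calibrated to 8–20 min, median 17), professional survey takers, bots
  submitting in waves (3 responses every 5 minutes), and brute-force screener
  probe streams, so the whole pipeline is testable with no real data.

## Worked example

Simulate a 40-respondent cohort (70% legitimate, 10% professional, 20% bot),
run every detector, and score it:

```r
library(surveyguard)

zm     <- generate_zip_county_map(n_counties = 24, n_eligible = 8, seed = 7)
cohort <- generate_cohort(cohort_config(n_total = 40, seed = 7), zm)
refs   <- list(zip_map = zm, calendar = default_channel_calendar(),
               speedbump_key = default_speedbump_key())

reports <- run_pipeline(cohort$screeners, cohort$surveys, refs)
m <- merge(reports, cohort$labels, by = "record_id")
table(m$archetype, m$label)
#>                fraudulent legitimate
#>   bot                   8          0
#>   legitimate            0         28
#>   professional          4          0
```

Every simulated fraudster is caught and no legitimate respondent is flagged.
A flagged bot record looks like this — 11 points from eight indicators:

```r
reports[reports$label == "fraudulent", ][1, ]
#>   record_id total_points label      fired_rules
#> 1 R00001              11 fraudulent cluster;dup_ip;dup_text;geo_simultaneous;od…
```

The cohort summary counts records with timestamp information, client/server
disparities, per-rule flags, and the fraudulent total:

```r
cat(format_summary(summarize_cohort(cohort$screeners, cohort$surveys, reports)), sep = "\n")
#> total_records                 80
#> with_timestamp_info           80
#> any_disparity                 14
#> disparity_over_60min          14
#> flagged_cluster                6
#> ...
#> flagged_tz_disparity           7
#> flagged_wave                   8
#> fraudulent                    12
```

(`any_disparity` is 14, not 16: by default one bot in five spoofs its client
clock to match the server and evades the time-zone rule — it is still caught
on its other indicators.)

Eligibility screening and CSV-in/CSV-out runs are available as
`screen_eligibility()` / `cmd_screen()`, `cmd_score()` and `cmd_simulate()`,
or from a shell via `inst/cli/surveyguard.R`; `inst/extdata/config.yaml` is a
working configuration.

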