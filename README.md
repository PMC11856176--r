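# pmintr

Minimum post-mortem interval (PMI-min) estimation from insect development
data, for forensic entomologists and death investigators.

When a body is found beyond the 48–72 h window in which livor, algor and
rigor mortis are informative, the insects on it still keep time: blowflies
colonize remains within hours to days of death, and their larvae develop at
temperature-predictable rates. The developmental stage of the oldest
insects collected at the scene therefore dates the earliest possible
colonization — a lower bound on the post-mortem interval.

`pmintr` implements the full chain:

* **Scene-temperature retrodiction** — fit a station→scene correction
  model (quadratic regression or RBF-kernel support-vector regression with
  environmental covariates) on ≥ 48 h of paired logger/weather-station
  records, compare candidates by MAD and RMSE, and retrodict hourly scene
  temperatures over the pre-discovery window.
* **Thermal-summation development** — accumulated degree hours
  `ADH = Σ max(T − T_base, 0)·Δt` with per-species cumulative stage-entry
  thresholds; at constant temperature, time to a stage is
  `ADH_stage / (T − T_base)`.
* **Oviposition back-calculation** — walk backward from the collection
  time consuming the observed oldest stage's threshold, emitting the full
  stage-entry timeline and the latest compatible oviposition time.
* **PCI adjustment and discrepancy** — extend the death-time bound by a
  published minimum pre-colonization interval matched on species and
  temperature band, and report the signed gap against a
  last-known-activity reference at that reference's own granularity
  (hours for timestamped references, whole calendar days for date-only
  ones).
* **Synthetic scenarios** — generators for diurnal station series, paired
  logger data and simulated colonization with known ground truth, so the
  whole pipeline is testable end to end.

Three fully worked urban death-investigation case fixtures ship with the
package, together with the COI identification roster of their 24 specimens
(*Lucilia sericata* and *Chrysomya megacephala*) and case-calibrated
development laws.

## A worked example

The second packaged case: third-instar *L. sericata* and *C. megacephala*
larvae collected 12 August 2022 at 14:50, corrected mean scene temperature
28.9 °C, last known activity a phone call on 7 August.

```r
library(pmintr)

fx  <- busan_case(2)
est <- estimate_pmi_min(fx$case, fx$datasets, pci = busan_pci_rules())
est
#> <pmi_estimate> busan-2022-case2
#>   reference species: Lucilia sericata (oldest stage: instar3)
#>   mean scene temperature: 28.9 °C
#>   oviposition (PMI-min bound): 2022-08-09 03:50
#>   PMI-min: 83 h before collection (2022-08-12 14:50)
#>   discrepancy vs reference: 2 days
#>   PCI: not applied

tidy(est)
#> # A tibble: 4 × 2
#>   stage   entry_time
#>   <chr>   <dttm>
#> 1 egg     2022-08-09 03:50:00
#> 2 instar1 2022-08-09 23:50:00
#> 3 instar2 2022-08-10 21:50:00
#> 4 instar3 2022-08-12 14:50:00
```

Reading the output: *L. sericata* is chosen as reference because it is the
slower developer to third instar at 28.9 °C (83 h vs 46 h for
*C. megacephala*), so it must have arrived first. Consuming 83 h of
development backward from collection puts oviposition at 03:50 on
9 August — the PMI-min bound. The phone-record reference carries only a
date, so the discrepancy is counted in whole calendar days: 2. The PCI
rule for *L. sericata* (0.2 day, 14.0–25.1 °C) does not fire at 28.9 °C.
For the third case (21.6 °C) it does, shrinking a 1-day gap to
24 − 0.2 × 24 = 19.2 h.

`autoplot(est)` draws the timeline; `glance(est)` returns the one-row
summary; `write_report(est, "case2.json")` writes the machine-readable
record plus a human-readable text report.

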