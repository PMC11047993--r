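# synthchip

A desk-scale simulator for a high-throughput electrochemical DNA-synthesis
chip, written for people designing or studying DNA-data-storage writers.
The platform it models combines two subsystems on one die:

* **A DRAM-like addressing fabric.**  3163 × 3163 ≈ 10⁷ electrode units at a
  3.16 µm pitch (10⁷/cm²), each a storage capacitor (C = 1 pF) behind an
  access transistor.  A 12-bit row decoder and 128 column sub-decoders
  sharing a 5-bit offset bus give individual addressability of all 10⁷
  units through 12 + 128 + 5 = 145 external pins; one drive instance selects
  up to 128 units of one row.  A full refresh pass is
  79 075 instances × 80 ns = 6.326 ms.
* **Per-unit RC voltage dynamics.**  A single-pole model with the
  on-resistance calibrated from the printed operating point
  V(t) = V_dd (1 − e^(−t/R_on C)), R_on = t_on / (C ln(V_dd/(V_dd−V_target)))
  ≈ 87.3 kΩ for (80 ns, 3 V, 5 V, 1 pF); the same pole gives ~1 V at 20 ns,
  and leakage droop over a refresh period stays inside the 5 % ripple
  budget.
* **Static-droplet-array (SDA) microfluidics.**  A 2D incompressible
  two-phase solver (MAC grid, projection method, conservative level-set
  interface capture, CSF surface tension, 135° contact-angle walls)
  simulates the capillary-valve unit array in which an aqueous plug,
  driven at 3 mm/s by fluorocarbon oil, leaves one isolated droplet in
  every reaction chamber — the physical mechanism that confines
  electrochemically generated protons to single sites.

A synthesis orchestrator ties the pieces together: it turns per-site target
oligonucleotides (FASTA) into per-cycle, per-base activation masks, schedules
them through the fabric, and audits deprotection against the droplet census.

## Worked example

```r
library(synthchip)

g <- array_geometry()                       # the 3163 x 3163 default fabric
g$n_pins                                    # 145
decode_columns(44, "0b01011", g)            # 1111  (44*25 + 11)
select_units(pin_vector("0b001010011010", 44, "0b01011", g), g)
#   row  col
# 1 666 1111

scan_time(full_scan_schedule(g), signif_digits = 2)   # 0.0063 s
group_lower_bound(2.5e6, 128)                         # 19532

p <- rc_params()                            # R_on calibrated: 87.3 kOhm
charge_voltage(c(20e-9, 80e-9), p)          # 1.024 3.000  (volt)
steady_state_ripple()$droop_pct             # 2.499  (% per 6.326 ms pass)

run <- run_to_steady(sda_geometry(), t_max = 46)   # default 4x4 array (~10 min)
column_means(run$census)
#    unit_x mean_area_um2
# 1:      0          1.82   <- inlet-nearest column, slightly larger
# 2:      1          1.72
# 3:      2          1.72
# 4:      3          1.75
all(run$census$confined)                    # TRUE: one droplet per chamber

jobs <- load_jobs(gen_random_oligos(16, 60, seed = 1), array_geometry(4, 4, 2))
run_synthesis(jobs, array_geometry(4, 4, 2))
# <synthesis_report> 60 cycles, 960 base couplings over 240 sub-steps ...
```

The numbers mean: every electrode of the 10-million-site array is reachable
through 145 pins; a held deprotection voltage ripples by ~2.5 % between
refreshes; and on the default geometry every chamber traps one confined
droplet of ~1.7–1.8 µm², with the inlet-nearest column slightly larger —
the droplet pattern that isolates each synthesis site chemically.

A command-line front end ships in `inst/cli/synthchip`
(`schedule`, `scan-time`, `pins`, `waveform`, `ripple`, `droplets`,
`synthesize`, `gen` subcommands).

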