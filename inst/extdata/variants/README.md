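Variant configurations for the canonical perturbation conditions.
Load with `load_config()`; pair with the schedule noted below.

- `low_motor.yaml`    — NMII reduced to 0.4 uM (network fails to contract);
                        schedule: `make_schedule("i")`.
- `low_linker.yaml`   — alpha-actinin reduced to 0.4 uM (bundle detaches
                        from the free pool); schedule: `make_schedule("i")`.
- short-interval      — `make_schedule("i", interval = 10)` with either
                        preset (10 s between pulls; no config change).
- static probe        — `make_schedule("i", step = 0)` keeps anchors with a
                        stationary probe (no config change).
- probe release       — `make_schedule("i", release_probe_at = 601)`
                        detaches anchored filaments after the fourth pull.
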