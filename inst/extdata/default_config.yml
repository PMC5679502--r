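# Reference batch-fermentation configuration for the bundled toy network.
# Every kinetic parameter is annotated with its provenance:
#   [literature] transport/enzyme kinetics taken from published assays
#   [fitted]     calibrated against batch fermentation time-series
# Rates in mmol gDW^-1 h^-1, Michaelis/inhibition constants in mM.

simulation:
  dt: 0.016666666666666666   # Euler time-step, 1/60 h
  duration: 192              # simulated hours after the start offset
  start_offset: 18           # spore germination lag: simulation clock zero
                             # sits 18 h after inoculation
  initial_biomass: 0.3125    # gDW/L at germination
  initial_pH: 2
  glucose: 160               # g/L
  xylose: 0                  # g/L
  phosphate: 0.17            # g/L (as PO4)
  citrate: 0                 # g/L
  knockouts: []              # subset of [oah, gox]

parameters:
  # phosphate
  v_Pe_max: 0.08             # [fitted] external phosphate max input rate
  K_Pe: 0.0333               # [fitted] external phosphate Michaelis constant
  v_P_max: 0.0008            # [fitted] stored-phosphate max release rate
  K_P: 0.0833                # [fitted] stored-phosphate Michaelis constant
  pie_after_8h_pH2: 0.015    # [fitted] phosphate input rate from 8 h, pH-2 start
  pie_after_8h_pH7: 0.004    # [fitted] phosphate input rate from 8 h, pH-7 start
  pie_switch_time: 8         # [fitted] hours after simulation start
  # glucose
  v_G1: 0.00031419           # [fitted] passive diffusion, per mM glucose
  v_G2_max: 0.186            # [literature] high-affinity transport max rate
  K_G2: 0.26                 # [literature] high-affinity Michaelis constant
  K_i2: 933                  # [literature] high-affinity citrate inhibition
  v_G3_max: 2.706            # [literature] low-affinity transport max rate
  K_G3: 3.67                 # [literature] low-affinity Michaelis constant
  K_i3: 233.21               # [literature] low-affinity citrate inhibition
  # xylose
  v_X1: 0.00033              # [fitted] passive diffusion, per mM xylose
  v_X2_max: 0.2              # [fitted] high-affinity transport max rate
  K_X2: 3.33                 # [fitted] high-affinity Michaelis constant
  v_X3_max: 2.5              # [fitted] low-affinity transport max rate
  K_X3: 3.33                 # [fitted] low-affinity Michaelis constant
  # glucose oxidase
  v_GOX_coef: 27.48          # [literature] max rate per mg enzyme
  K_GOX: 33                  # [literature] Michaelis constant
  GOX_conc: 0.1              # [fitted] enzyme loading, mg gDW^-1
  # secretion caps
  v_CIT: 0.12                # [fitted] citrate output cap, initial pH <= 2
  v_CIT_high_pH: 0.016       # [fitted] citrate output cap, initial pH > 2
  v_OXAL: 0.01               # [fitted] oxalate output cap (0 below pH 2)

network: toy
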