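# Static load-case battery: upright standing, anterior holds, trunk
# flexion without and with a hand load, and arm elevation.  Offsets are
# measured anteriorly from the named reference point ("chest" on the
# thorax, "sacrum" at the sacral endplate); the held mass is rigidly
# attached to the thorax.
- name: standing
- name: standing_20kg_20cm_chest
  hand_mass_kg: 20
  load_offset_mm: 200
  reference: chest
- name: standing_20kg_55cm_sacrum
  hand_mass_kg: 20
  load_offset_mm: 550
  reference: sacrum
- name: flexion_30
  trunk_flexion_deg: 30
- name: arms_elevated
  arms_elevated: yes
- name: flexion_10
  trunk_flexion_deg: 10
- name: flexion_10_10kg
  trunk_flexion_deg: 10
  hand_mass_kg: 10
  load_offset_mm: 300
  reference: chest
- name: flexion_20
  trunk_flexion_deg: 20
- name: flexion_20_10kg
  trunk_flexion_deg: 20
  hand_mass_kg: 10
  load_offset_mm: 300
  reference: chest
- name: flexion_30_10kg
  trunk_flexion_deg: 30
  hand_mass_kg: 10
  load_offset_mm: 300
  reference: chest
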