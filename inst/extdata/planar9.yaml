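# Default planar sagittal lower-limb model: 3 DOFs, 9 muscle groups.
# Sign conventions: hip/knee extension positive, ankle plantarflexion
# positive; angles in radians, zero at quiet standing.
# Grouped maximal isometric forces follow a standard generic lower-limb
# musculoskeletal model; optimal_angle places each group's fiber at optimal
# length in the posture where its ADL demand peaks (rigid-tendon model).
name: planar9
body_mass: 61.0
gravity: 9.81
dofs:
  - {name: hip,   positive_direction: extension,      axis_sign: -1, ref_offset: 0.0}
  - {name: knee,  positive_direction: extension,      axis_sign:  1, ref_offset: 0.0}
  - {name: ankle, positive_direction: plantarflexion, axis_sign: -1, ref_offset: 1.5707963}
segments:
  # anthropometric fractions (mass of body mass; com/gyration of length)
  - {name: thigh, mass_fraction: 0.1000, length: 0.42, com_fraction: 0.433, gyration_fraction: 0.323}
  - {name: shank, mass_fraction: 0.0465, length: 0.42, com_fraction: 0.433, gyration_fraction: 0.302}
  - {name: foot,  mass_fraction: 0.0145, length: 0.22, com_fraction: 0.500, gyration_fraction: 0.475}
muscles:
  - name: glut_max
    max_isometric_force: 2400
    optimal_fiber_length: 0.15
    dofs:
      - {name: hip, moment_arm: [0.055, 0.008], optimal_angle: -1.0}
  - name: iliopsoas
    max_isometric_force: 2186
    optimal_fiber_length: 0.12
    dofs:
      - {name: hip, moment_arm: [-0.05, 0.005], optimal_angle: -0.4}
  - name: hamstrings
    max_isometric_force: 2594
    optimal_fiber_length: 0.12
    dofs:
      - {name: hip,  moment_arm: [0.055],        optimal_angle: -0.5}
      - {name: knee, moment_arm: [-0.03, 0.008], optimal_angle: -0.5}
  - name: rect_fem
    max_isometric_force: 1169
    optimal_fiber_length: 0.13
    dofs:
      - {name: hip,  moment_arm: [-0.04],        optimal_angle: -0.7}
      - {name: knee, moment_arm: [0.045, 0.010], optimal_angle: -0.7}
  - name: vasti
    max_isometric_force: 4530
    optimal_fiber_length: 0.10
    dofs:
      - {name: knee, moment_arm: [0.045, 0.010], optimal_angle: -1.1}
  - name: bifemsh
    max_isometric_force: 804
    optimal_fiber_length: 0.17
    dofs:
      - {name: knee, moment_arm: [-0.03], optimal_angle: -0.5}
  - name: gastroc
    max_isometric_force: 2241
    optimal_fiber_length: 0.09
    dofs:
      - {name: knee,  moment_arm: [-0.02],         optimal_angle: -0.3}
      - {name: ankle, moment_arm: [0.045, -0.010], optimal_angle: -0.05}
  - name: soleus
    max_isometric_force: 5137
    optimal_fiber_length: 0.05
    dofs:
      - {name: ankle, moment_arm: [0.040, -0.005], optimal_angle: -0.05}
  - name: tib_ant
    max_isometric_force: 905
    optimal_fiber_length: 0.098
    dofs:
      - {name: ankle, moment_arm: [-0.035], optimal_angle: -0.1}
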