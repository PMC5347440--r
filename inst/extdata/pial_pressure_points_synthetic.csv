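source,diameter_um,pressure_mmhg
harper,15,45
harper,25,52
harper,40,60
harper,60,68
werber,20,48
werber,35,57
werber,50,63
werber,70,70
hudetz,10,38
hudetz,30,55
hudetz,45,61
shapiro,12,40
shapiro,28,54
shapiro,55,65
shapiro,80,73
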