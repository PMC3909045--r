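test_system,marker,count
mice/in vivo,IL-2,3
mice/in vivo,IFN-g,120
mice/in vivo,IL-4,113
mice/in vivo,IL-13,1
mice/in vitro/cell-cell,IL-2,87
mice/in vitro/cell-cell,IFN-g,77
mice/in vitro/cell-cell,IL-4,67
mice/in vitro/cell-cell,IL-13,13
mice/in vitro/cell-plate,IL-2,66
mice/in vitro/cell-plate,IFN-g,1
mice/in vitro/cell-plate,IL-4,1
mice/in vitro/cell-plate,IL-13,1
human/in vitro/cell-cell,IL-2,19
human/in vitro/cell-cell,IFN-g,121
human/in vitro/cell-cell,IL-4,96
human/in vitro/cell-cell,IL-13,56
human/in vitro/cell-plate,IL-2,5
human/in vitro/cell-plate,IFN-g,2
human/in vitro/cell-plate,IL-4,1
human/in vitro/cell-plate,IL-13,1
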