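CNG001
CNG002
CNG003
CNG004
CNG005
CNG006
CNG007
CNG008
CNG009
CNG010
CNG011
CNG012
CNG013
CNG014
CNG015
CNG016
CNG017
CNG018
CNG019
CNG020
CNG021
CNG022
CNG023
CNG024
CNG025
CNG026
CNG027
CNG028
CNG029
CNG030
CNG031
CNG032
CNG033
CNG034
CNG035
CNG036
CNG037
CNG038
CNG039
CNG040
CNG041
CNG042
CNG043
CNG044
CNG045
CNG046
CNG047
CNG048
CNG049
CNG050
CNG051
CNG052
CNG053
CNG054
CNG055
CNG056
CNG057
CNG058
CNG059
CNG060
CNG061
CNG062
CNG063
CNG064
CNG065
CNG066
CNG067
CNG068
CNG069
CNG070
CNG071
CNG072
CNG073
CNG074
CNG075
CNG076
CNG077
CNG078
CNG079
CNG080
CNG081
CNG082
CNG083
CNG084
CNG085
CNG086
CNG087
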