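{"sugar":{"name":"sugar","high_names":["C1'","C2'","C3'","C4'","O4'","C5'","O3'","N9"],"high":[[0.50730047,-0.05623085,1.1164198],[-0.96123823,0.17846147,0.85765832],[-1.08207025,-0.0087288,-0.69388588],[0.33980883,-0.3283366,-1.15223807],[1.19619918,0.21483479,-0.12795416],[0.64615156,0.31578317,-2.51004565],[-2.00699431,-1.05194952,-0.97938077],[0.99507339,0.81119058,2.15206623]],"low":[[-2,4.5,-0.5],[3.5,-4,0],[-3.5,4,0],[-2.5,4.5,1.5],[3,-4,2],[4.5,-2.5,2],[-3.5,3,-3.5],[-5.5,2,1]],"frame_names":["P","OP1","OP2","O5'","C5'","C4'","O4'","C3'","O3'","C2'","O2'","C1'","N9"],"frame":[[2.23352454,0.75737593,-4.29526],[1.99602262,2.21165544,-4.16946],[1.21784772,0.138953,-5.37976],[1.99191122,0.04921001,-2.86986],[0.63811128,0.31138453,-2.50116],[0.34196092,-0.33589459,-1.14746],[1.19428033,0.2230493,-0.12476],[-1.09479549,-0.00243926,-0.69036],[-1.9819997,-1.07919728,-0.99656],[-0.97013545,0.17895637,0.83924],[-1.77809387,-0.77931028,1.52554],[0.52868969,-0.06367181,1.12334],[1.00242034,0.84009368,2.17344]]},"phosphate":{"name":"phosphate","high_names":["P","OP1","OP2","O5'","O3'"],"high":[[0.1461842,-0.28392545,-0.19624343],[-0.07603298,1.1669553,-0.05867349],[-0.84898137,-0.92285313,-1.25329881],[-0.09448002,-1.00814347,1.21533484],[0.87331018,1.04796676,0.29288089]],"low":[[-4.5,2,-2],[-1.5,2.5,-4.5],[2,-5,-0.5],[-3,3,-3.5],[2,-4.5,-2.5]],"frame_names":["P","OP1","OP2","O5'","O3'"],"frame":[[0.15553514,-0.29437676,-0.19108],[-0.08196678,1.15990275,-0.06528],[-0.86014168,-0.9127997,-1.27558],[-0.08607819,-1.00254268,1.23432],[0.87265151,1.04981638,0.29762]]}}
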