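PreopSphere,PreopCylinder,PreopAxis,PreopVertex,TargetSphere,TargetCylinder,TargetAxis,TargetVertex,PostopSphere,PostopCylinder,PostopAxis,PostopVertex
-0.50,-1.25,10,12,0,0,0,12,0.00,-0.25,100,12
-1.00,-0.75,95,12,0,0,0,12,-0.25,0.00,0,12
-2.00,-1.50,170,12,0,0,0,12,-0.50,,20,12
-1.75,-1.00,45,12,0,0,0,12,-0.25,-0.25,50,12
-1.00,-1.00,45,12,-1.00,-1.00,45,12,-0.50,-0.50,40,12
-2.50,-2.00,5,12,0,0,0,12,-0.75,-0.50,10,12
-1.25,,60,12,0,0,0,12,-0.25,-0.25,65,12
-0.75,-1.75,120,12,0,0,0,12,0.00,-0.50,115,12
-1.50,-0.50,30,12,0,0,0,12,-0.50,-0.25,35,12
-2.00,-1.25,150,12,0,0,0,12,-0.25,-0.50,145,12
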